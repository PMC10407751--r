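make_portfolio <- function(n = 3) {
  tibble::tibble(
    clinic_id = as.character(seq_len(n)),
    dist = replicate(n, clinic1_dist(), simplify = FALSE),
    costs = replicate(n, cost_schedule(), simplify = FALSE)
  )
}

test_that("portfolio total is the sum of independent per-clinic optima", {
  single <- optimize_portfolio(make_portfolio(1), candidates = 1:10)
  expect_equal(single$total_expected_loss, 35 * 185 / 88)
  expect_equal(single$plans$optimal_r, 6)

  twin <- optimize_portfolio(make_portfolio(2), candidates = 1:10)
  expect_equal(twin$total_expected_loss, 2 * single$total_expected_loss)
  expect_equal(twin$plans$clinic_id, c("1", "2"))

  expect_error(optimize_portfolio(make_portfolio(0)), "at least one")
  dup <- make_portfolio(2); dup$clinic_id <- c("a", "a")
  expect_error(optimize_portfolio(dup), "Duplicate")
})

test_that("portfolio total is permutation-invariant and order-preserving", {
  set.seed(5)
  clinics <- tibble::tibble(
    clinic_id = c("x", "y", "z"),
    dist = replicate(3, noshow_distribution(random_freq_table(8)),
                     simplify = FALSE),
    costs = replicate(3, random_cost_general(), simplify = FALSE)
  )
  fwd <- optimize_portfolio(clinics)
  rev <- optimize_portfolio(clinics[3:1, ])
  expect_equal(rev$total_expected_loss, fwd$total_expected_loss)
  expect_equal(rev$plans$clinic_id, c("z", "y", "x"))
})

test_that("row minima of supplied curves agree with re-optimization", {
  clinics <- make_portfolio(3)
  rep <- optimize_portfolio(clinics, candidates = 1:10)
  res <- summarize_row_minima(
    dplyr::select(rep$curves, clinic_id, overbooked, expected_loss))
  expect_equal(res$minima$optimal_r, rep$plans$optimal_r)
  expect_equal(res$total, rep$total_expected_loss)
})

test_that("published 14-clinic curves give the bolded optima and total", {
  curves <- example_loss_curves()
  res <- summarize_row_minima(curves)
  expect_equal(res$minima$clinic_id, as.character(1:14))
  expect_equal(res$minima$optimal_r,
               c(6, 5, 5, 5, 6, 4, 5, 4, 4, 5, 4, 4, 3, 4))
  expect_equal(res$total, 2337.74, tolerance = 1e-9)
  expect_lte(res$total, 2408)

  one <- summarize_row_minima(tibble::tibble(
    clinic_id = "a", overbooked = 1:3, expected_loss = c(5, 3, 4)))
  expect_equal(one$minima$expected_loss, 3)
  expect_equal(one$total, 3)
  zero <- summarize_row_minima(tibble::tibble(
    clinic_id = c("a", "b"), overbooked = c(1L, 1L),
    expected_loss = c(0, 0)))
  expect_equal(zero$total, 0)
  expect_error(summarize_row_minima(curves[0, ]), "no rows")
})

test_that("baseline comparison prices a fixed level for every clinic", {
  clinics <- make_portfolio(2)
  rep <- optimize_portfolio(clinics, candidates = 1:10, baseline_r = 1)
  expect_equal(rep$baseline_loss, 2 * 35 * 377 / 88)
  expect_gte(rep$baseline_loss, rep$total_expected_loss)
})

test_that("portfolio tidiers and plot summarize the report", {
  rep <- optimize_portfolio(make_portfolio(2), candidates = 1:10)
  expect_equal(nrow(tidy(rep)), 20)
  g <- glance(rep)
  expect_equal(g$n_clinics, 2)
  expect_true(is.na(g$baseline_loss))
  expect_s3_class(autoplot(rep), "ggplot")
})
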