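test_that("loss cells price mismatches per mode", {
  sym <- cost_schedule()
  expect_equal(loss_cell(10, 1, sym), 315)
  expect_equal(loss_cell(0, 0, sym), 0)
  expect_equal(loss_cell(3, 3, sym), 0)
  expect_equal(loss_cell(c(1, 5), c(4, 2), sym), c(105, 105))

  gen <- cost_schedule(mode = "general_piecewise", idle_cost = 10,
                       overage_cost = 3)
  expect_equal(loss_cell(7, 2, gen), 50)  # 5 idle slots
  expect_equal(loss_cell(2, 7, gen), 15)  # 5 bumped patients

  lit <- cost_schedule(mode = "literal_eq5", consultation_fee = 300,
                       overbooking_cost = 70)
  expect_equal(loss_cell(1, 1, lit), abs(335 - 370))
  expect_equal(loss_cell(0, 0, lit), 0)

  expect_error(loss_cell(-1, 2, sym), "must be >=")
  expect_error(cost_schedule(mode = "literal_eq5"), "needs")
})

test_that("loss matrix applies cells over the S x R grid", {
  m <- build_loss_matrix(1:3, 1:3, cost_schedule(operation_cost = 1))
  wide <- loss_matrix_wide(m)
  expect_equal(as.matrix(wide[, c("r_1", "r_2", "r_3")]),
               abs(outer(1:3, 1:3, "-")), ignore_attr = TRUE)
  # symmetric mode: exchanging S and R leaves the cell unchanged
  swapped <- m |>
    dplyr::rename(no_shows = overbooked, overbooked = no_shows) |>
    dplyr::arrange(no_shows, overbooked)
  expect_equal(dplyr::arrange(tibble::as_tibble(m), no_shows, overbooked)$loss,
               swapped$loss)
  one <- build_loss_matrix(3, 3, cost_schedule())
  expect_equal(one$loss, 0)
})

test_that("expected loss is the pmf-weighted column sum", {
  d <- clinic1_dist()
  expect_equal(expected_loss(d, 6), 35 * 185 / 88)
  expect_equal(expected_loss(d, 1), 35 * 377 / 88)
  deg <- noshow_distribution(tibble::tibble(no_shows = 4L, frequency = 3L))
  expect_equal(expected_loss(deg, 4), 0)
  # linearity in the unit cost
  k <- 7.5
  expect_equal(expected_loss(d, 3, cost_schedule(operation_cost = 35 * k)),
               k * expected_loss(d, 3))
})

test_that("expected loss matches an independent enumeration oracle", {
  set.seed(19)
  for (i in 1:25) {
    freq <- random_freq_table(sample(3:12, 1))
    d <- noshow_distribution(freq)
    idle <- sample(1:80, 1); over <- sample(1:80, 1)
    costs <- cost_schedule(mode = "general_piecewise", idle_cost = idle,
                           overage_cost = over)
    r <- sample(0:12, 1)
    expect_equal(expected_loss(d, r, costs),
                 expected_loss_by_enumeration(freq, r, idle, over))
  }
})

test_that("optimizer picks the least-loss level with ties broken low", {
  d <- clinic1_dist()
  plan <- optimize_overbooking(d, candidates = 1:10)
  expect_equal(plan$optimal_r, 6)
  expect_equal(plan$optimal_expected_loss, min(plan$curve$expected_loss))

  deg <- noshow_distribution(tibble::tibble(no_shows = 4L, frequency = 1L))
  expect_equal(optimize_overbooking(deg, candidates = 1:10)$optimal_r, 4)

  # two equal atoms: the expected loss is flat between them, tie -> lowest
  two <- noshow_distribution(tibble::tibble(no_shows = c(2L, 8L),
                                            frequency = c(1L, 1L)))
  plan2 <- optimize_overbooking(two, candidates = 1:10)
  expect_equal(plan2$optimal_r, 2)
  flat <- plan2$curve$expected_loss[plan2$curve$overbooked %in% 2:8]
  expect_equal(flat, rep(flat[1], 7))

  expect_error(optimize_overbooking(d, candidates = integer()), "nonempty")
})

test_that("expected loss is discretely convex in the overbooking level", {
  set.seed(23)
  for (i in 1:40) {
    d <- noshow_distribution(random_freq_table(sample(3:12, 1)))
    costs <- random_cost_general()
    curve <- expected_loss(d, 0:(max(d$no_shows) + 3), costs)
    expect_true(all(diff(diff(curve)) >= -1e-9))
  }
})

test_that("critical fractile reproduces the newsvendor ratio", {
  expect_equal(critical_fractile(cost_schedule()), 0.5)
  expect_equal(critical_fractile(
    cost_schedule(mode = "general_piecewise", idle_cost = 90,
                  overage_cost = 10)), 0.9)
  expect_error(critical_fractile(
    cost_schedule(mode = "literal_eq5", consultation_fee = 1,
                  overbooking_cost = 1)), "no critical fractile")
  # symmetric costs: the optimum is the distribution median
  d <- clinic1_dist()
  expect_equal(noshow_quantile(d, critical_fractile(cost_schedule())), 6)
  expect_equal(optimize_overbooking(d, candidates = 0:10)$optimal_r, 6)
})

test_that("brute-force optimum equals the critical-fractile quantile", {
  set.seed(31)
  for (i in 1:200) {
    d <- noshow_distribution(random_freq_table(sample(2:12, 1)))
    costs <- random_cost_general()
    plan <- optimize_overbooking(d, costs, candidates = 0:max(d$no_shows))
    oracle <- noshow_quantile(d, critical_fractile(costs))
    expect_equal(plan$optimal_r, oracle)
  }
})

test_that("scaling both unit costs rescales losses but not the optimum", {
  set.seed(37)
  for (k in c(0.25, 3, 117)) {
    d <- noshow_distribution(random_freq_table(8))
    base <- cost_schedule(mode = "general_piecewise", idle_cost = 12,
                          overage_cost = 30)
    scaled <- cost_schedule(mode = "general_piecewise", idle_cost = 12 * k,
                            overage_cost = 30 * k)
    p1 <- optimize_overbooking(d, base)
    p2 <- optimize_overbooking(d, scaled)
    expect_equal(p2$optimal_r, p1$optimal_r)
    expect_equal(p2$curve$expected_loss, k * p1$curve$expected_loss)
  }
})

test_that("shifting the support shifts the symmetric-cost optimum", {
  set.seed(41)
  for (i in 1:10) {
    freq <- random_freq_table(sample(3:8, 1))
    shift <- sample(1:5, 1)
    shifted <- dplyr::mutate(freq, no_shows = no_shows + shift)
    p0 <- optimize_overbooking(noshow_distribution(freq),
                               candidates = 0:20)
    p1 <- optimize_overbooking(noshow_distribution(shifted),
                               candidates = 0:20)
    expect_equal(p1$optimal_r, p0$optimal_r + shift)
  }
})

test_that("plan tidiers and plot expose the curve", {
  plan <- optimize_overbooking(clinic1_dist(), candidates = 1:10,
                               clinic_id = "1")
  td <- tidy(plan)
  expect_equal(sum(td$optimal), 1)
  expect_equal(td$overbooked[td$optimal], 6)
  g <- glance(plan)
  expect_equal(g$optimal_r, 6)
  expect_equal(g$clinic_id, "1")
  expect_s3_class(autoplot(plan), "ggplot")
})
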