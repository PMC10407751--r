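test_that("pmf is frequency over total days, at full precision", {
  # a count seen on 4 of 30 days has probability 4/30
  freq <- tibble::tibble(no_shows = c(7L, 3L), frequency = c(4L, 26L))
  d <- noshow_distribution(freq)
  expect_equal(d$pmf[d$no_shows == 7], 4 / 30)
  expect_equal(n_observations(d), 30)

  d1 <- clinic1_dist()
  expect_equal(d1$pmf[1], 10 / 88)
  expect_equal(round(d1$pmf[1], 2), 0.11)
  expect_equal(sum(d1$pmf), 1, tolerance = 1e-12)

  degenerate <- noshow_distribution(
    tibble::tibble(no_shows = 5L, frequency = 9L))
  expect_equal(degenerate$pmf, 1)
  expect_equal(degenerate$cdf, 1)
})

test_that("unobserved interior counts get dense zero-probability support", {
  freq <- tibble::tibble(no_shows = c(2L, 5L), frequency = c(3L, 1L))
  d <- noshow_distribution(freq)
  expect_equal(d$no_shows, 2:5)
  expect_equal(d$pmf, c(3 / 4, 0, 0, 1 / 4))
})

test_that("degenerate and invalid frequency tables are rejected", {
  expect_error(noshow_distribution(
    tibble::tibble(no_shows = 1:2, frequency = c(0L, 0L))), "zero")
  expect_error(noshow_distribution(
    tibble::tibble(no_shows = 1L, frequency = -2L)), "must be >=")
  expect_error(noshow_distribution(
    tibble::tibble(no_shows = c(1L, 1L), frequency = c(1L, 2L))), "distinct")
  expect_error(noshow_distribution(clinic1_freq()[0, ]), "no rows")
})

test_that("cdf_at steps through the running sum with saturated tails", {
  d <- clinic1_dist()
  expect_equal(cdf_at(d, 2), 16 / 88)
  expect_equal(round(cdf_at(d, 2), 2), 0.18)
  expect_equal(cdf_at(d, -1), 0)
  expect_equal(cdf_at(d, 0), 0)
  expect_equal(cdf_at(d, max(d$no_shows)), 1)
  expect_equal(cdf_at(d, 99), 1)
  expect_equal(cdf_at(d, c(1, 4, 6)), c(10, 36, 56) / 88)
})

test_that("quantile returns the smallest count reaching the target", {
  d <- clinic1_dist()
  expect_equal(noshow_quantile(d, 0.5), 6)
  expect_equal(noshow_quantile(d, 1), 10)
  expect_equal(noshow_quantile(d, 1e-9), 1)
  deg <- noshow_distribution(tibble::tibble(no_shows = 3L, frequency = 2L))
  expect_equal(noshow_quantile(deg, c(0.01, 0.5, 1)), c(3, 3, 3))
  expect_error(noshow_quantile(d, 0), "\\(0, 1\\]")
  expect_error(noshow_quantile(d, 1.2), "\\(0, 1\\]")
})

test_that("random frequency tables always yield a valid distribution", {
  set.seed(42)
  for (i in 1:50) {
    d <- noshow_distribution(random_freq_table(sample(1:15, 1)))
    expect_true(all(d$pmf >= 0 & d$pmf <= 1))
    expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
    expect_true(all(diff(d$cdf) >= -1e-15))
    expect_equal(d$cdf[length(d$cdf)], 1, tolerance = 1e-12)
    expect_equal(d$cdf, cumsum(d$pmf))
  }
})

test_that("quantile and cdf_at are mutually consistent", {
  set.seed(7)
  for (i in 1:30) {
    d <- noshow_distribution(random_freq_table(sample(2:12, 1)))
    for (q in runif(5, 0.01, 1)) {
      s <- noshow_quantile(d, q)
      expect_gte(cdf_at(d, s), q - 1e-9)
      expect_lt(cdf_at(d, s - 1), q)
    }
  }
})

test_that("appointment logs tally into frequency tables", {
  # 30-day log in which exactly 4 days have 7 no-shows
  log <- tibble::tibble(
    booked = rep(20L, 30),
    shows = c(rep(13L, 4), rep(18L, 26))
  )
  freq <- freq_from_log(log)
  expect_equal(freq$frequency[freq$no_shows == 7], 4)
  expect_equal(sum(freq$frequency), 30)

  same <- tibble::tibble(no_shows = rep(3L, 12))
  expect_equal(freq_from_log(same),
               tibble::tibble(no_shows = 3L, frequency = 12L))

  expect_error(freq_from_log(tibble::tibble(booked = 5L, shows = 6L)),
               "exceeds")
  expect_error(freq_from_log(tibble::tibble(no_shows = integer())),
               "at least one record")
})

test_that("tidy and glance expose the distribution as tibbles", {
  d <- clinic1_dist()
  td <- tidy(d)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("no_shows", "frequency", "pmf", "cdf"))
  g <- glance(d)
  expect_equal(g$n_obs, 88)
  expect_equal(g$mean_no_shows, sum((1:10) * clinic1_freq()$frequency) / 88)
  expect_equal(g$median_no_shows, 6)
})

test_that("autoplot returns a ggplot of the distribution", {
  p <- autoplot(clinic1_dist())
  expect_s3_class(p, "ggplot")
})
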