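#' Empirical distribution of daily no-show counts
#'
#' Turns an observed frequency table of daily no-show counts into an
#' empirical discrete distribution: for each count s observed on F_s of the
#' n recorded days, the probability mass is F_s / n and the CDF is the
#' running sum.  Probabilities are kept as exact fractions of n at full
#' precision; rounding happens only in display and reports.  The support is
#' made dense over the observed minimum..maximum, so interior counts never
#' seen in the data carry probability zero and the loss curve is evaluable
#' at every candidate overbooking level.
#'
#' @param freq Data frame with columns `no_shows` (distinct nonnegative
#'   integer counts) and `frequency` (nonnegative integer days observed; at
#'   least one must be positive).
#' @return An object of class `noshow_distribution`: a tibble with columns
#'   `no_shows`, `frequency`, `pmf`, `cdf` and attribute `n_obs` (total days
#'   observed).
#' @seealso [cdf_at()], [noshow_quantile()], [freq_from_log()]
#' @export
#' @examples
#' d <- noshow_distribution(example_noshow_freq())
#' d
#' glance(d)
noshow_distribution <- function(freq) {
  check_columns(freq, c("no_shows", "frequency"), "`freq`")
  if (nrow(freq) == 0L) {
    abort("`freq` has no rows; at least one observed day is required.")
  }
  check_number(freq$no_shows, "no_shows", min = 0, allow_fractional = FALSE)
  check_number(freq$frequency, "frequency", min = 0, allow_fractional = FALSE)
  if (anyDuplicated(freq$no_shows) > 0L) {
    abort("`no_shows` values must be distinct.")
  }
  n_obs <- sum(freq$frequency)
  if (n_obs <= 0) {
    abort("All frequencies are zero; cannot estimate a distribution.")
  }
  dense <- tibble(no_shows = seq(min(freq$no_shows), max(freq$no_shows))) |>
    dplyr::left_join(freq[, c("no_shows", "frequency")], by = "no_shows") |>
    dplyr::mutate(
      frequency = dplyr::coalesce(.data$frequency, 0),
      pmf = .data$frequency / n_obs,
      cdf = cumsum(.data$pmf)
    )
  new_noshow_distribution(dense, n_obs)
}

new_noshow_distribution <- function(tbl, n_obs) {
  structure(as_tibble(tbl), n_obs = n_obs,
            class = c("noshow_distribution", class(as_tibble(tbl))))
}

#' @export
print.noshow_distribution <- function(x, ...) {
  cat(sprintf("<noshow_distribution> %d days observed, support %d..%d\n",
              attr(x, "n_obs"), min(x$no_shows), max(x$no_shows)))
  NextMethod()
}

#' Number of observed days behind a no-show distribution
#' @param dist A [noshow_distribution()].
#' @return Integer count of days.
#' @export
n_observations <- function(dist) {
  stopifnot(inherits(dist, "noshow_distribution"))
  attr(dist, "n_obs")
}

#' Cumulative probability of at most `s` no-shows
#'
#' @param dist A [noshow_distribution()].
#' @param s Vector of counts; values below the support give 0, values at or
#'   above the maximum give 1.
#' @return P(S <= s), vectorized over `s`.
#' @export
#' @examples
#' d <- noshow_distribution(example_noshow_freq())
#' cdf_at(d, 2) # 16/88
cdf_at <- function(dist, s) {
  stopifnot(inherits(dist, "noshow_distribution"))
  check_number(s, "s")
  step <- stats::stepfun(dist$no_shows, c(0, dist$cdf), right = FALSE)
  pmin(step(s), 1)
}

#' Quantile of the no-show distribution
#'
#' Returns the smallest support value whose CDF reaches `q` -- the discrete
#' (left-continuous inverse) quantile.  Used with [critical_fractile()] as a
#' closed-form check of the brute-force overbooking optimizer.
#'
#' @param dist A [noshow_distribution()].
#' @param q Probabilities in (0, 1]; vectorized.
#' @return No-show counts, one per element of `q`.
#' @export
#' @examples
#' d <- noshow_distribution(example_noshow_freq())
#' noshow_quantile(d, 0.5) # 6
noshow_quantile <- function(dist, q) {
  stopifnot(inherits(dist, "noshow_distribution"))
  check_number(q, "q")
  if (any(q <= 0 | q > 1)) {
    abort("`q` must lie in (0, 1].")
  }
  # 1e-9 relative guard: running-sum CDFs can undershoot an exact fraction
  # by one ulp, which would otherwise push the quantile one support point up
  vapply(q, function(qi) {
    dist$no_shows[which(dist$cdf >= qi - 1e-9 * qi)[1]]
  }, numeric(1))
}

#' Tally an appointment log into a no-show frequency table
#'
#' Accepts a per-day log with either a `no_shows` column or `booked` and
#' `shows` columns (no-shows = booked - shows) and counts the number of days
#' on which each distinct no-show count occurred.
#'
#' @param log Data frame with one row per clinic-day.
#' @return Tibble with columns `no_shows` and `frequency`, sorted by count,
#'   suitable for [noshow_distribution()].
#' @export
#' @examples
#' log <- generate_log(n_days = 50, booked_per_day = 36,
#'                     show_model = "fixed_prob", show_prob = 0.9, seed = 1)
#' freq_from_log(log)
freq_from_log <- function(log) {
  if (!is.data.frame(log) || nrow(log) == 0L) {
    abort("`log` must be a data frame with at least one record.")
  }
  if (!("no_shows" %in% names(log))) {
    check_columns(log, c("booked", "shows"), "`log`")
    check_number(log$booked, "booked", min = 0, allow_fractional = FALSE)
    check_number(log$shows, "shows", min = 0, allow_fractional = FALSE)
    if (any(log$shows > log$booked)) {
      bad <- which(log$shows > log$booked)
      abort(sprintf("`shows` exceeds `booked` on row(s) %s.",
                    paste(head(bad, 5), collapse = ", ")))
    }
    log$no_shows <- log$booked - log$shows
  }
  check_number(log$no_shows, "no_shows", min = 0, allow_fractional = FALSE)
  log |>
    dplyr::count(.data$no_shows, name = "frequency") |>
    dplyr::arrange(.data$no_shows) |>
    as_tibble()
}

#' @export
tidy.noshow_distribution <- function(x, ...) {
  as_tibble(x)[, c("no_shows", "frequency", "pmf", "cdf")]
}

#' @export
glance.noshow_distribution <- function(x, ...) {
  tibble(
    n_obs = attr(x, "n_obs"),
    support_min = min(x$no_shows),
    support_max = max(x$no_shows),
    mean_no_shows = sum(x$no_shows * x$pmf),
    median_no_shows = noshow_quantile(x, 0.5)
  )
}

#' Plot an empirical no-show distribution
#'
#' Bars show the probability mass of each daily no-show count; the step line
#' overlays the CDF.
#'
#' @param object A [noshow_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.noshow_distribution <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$no_shows)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$pmf), fill = "steelblue",
                      alpha = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$cdf), direction = "hv",
                       colour = "grey30") +
    ggplot2::scale_x_continuous(breaks = object$no_shows) +
    ggplot2::labs(x = "daily no-shows", y = "probability",
                  title = sprintf("Empirical no-show distribution (%d days)",
                                  attr(object, "n_obs"))) +
    ggplot2::theme_minimal()
}
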