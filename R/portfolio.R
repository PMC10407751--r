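#' Optimize overbooking across a portfolio of clinics
#'
#' Runs [optimize_overbooking()] independently for each clinic (clinics
#' share no physicians or capacity) and totals the per-clinic optimal
#' expected losses.
#'
#' @param clinics Tibble with one row per clinic: a `clinic_id` column plus
#'   list-columns `dist` (each a [noshow_distribution()]) and `costs` (each
#'   a [cost_schedule()]).  A plain list of such rows is also accepted.
#' @param candidates Candidate overbooking levels shared by all clinics;
#'   `NULL` (default) lets each clinic use `0:max(its support)`.
#' @param baseline_r Optional fixed overbooking level applied to every
#'   clinic for a naive-baseline comparison; `NULL` skips the baseline.
#' @return An object of class `portfolio_report` with elements `plans`
#'   (tibble: `clinic_id`, `optimal_r`, `optimal_expected_loss`), `curves`
#'   (long tibble of every clinic's expected-loss curve),
#'   `total_expected_loss`, and `baseline_loss` (NA unless `baseline_r`
#'   given).
#' @export
#' @examples
#' freq <- example_noshow_freq()
#' clin <- tibble::tibble(
#'   clinic_id = c("1", "2"),
#'   dist = list(noshow_distribution(freq), noshow_distribution(freq)),
#'   costs = list(cost_schedule(), cost_schedule())
#' )
#' rep <- optimize_portfolio(clin, candidates = 1:10)
#' glance(rep)
optimize_portfolio <- function(clinics, candidates = NULL,
                               baseline_r = NULL) {
  check_columns(clinics, c("clinic_id", "dist", "costs"), "`clinics`")
  if (nrow(clinics) == 0L) {
    abort("`clinics` must contain at least one clinic.")
  }
  if (anyDuplicated(clinics$clinic_id) > 0L) {
    abort(sprintf("Duplicate clinic_id(s): %s.",
                  paste(unique(clinics$clinic_id[
                    duplicated(clinics$clinic_id)]), collapse = ", ")))
  }
  plans <- purrr::pmap(
    list(clinics$clinic_id, clinics$dist, clinics$costs),
    function(id, dist, costs) {
      optimize_overbooking(dist, costs, candidates = candidates,
                           clinic_id = as.character(id))
    }
  )
  plan_tbl <- purrr::map_dfr(plans, glance) |>
    dplyr::select("clinic_id", "optimal_r", "optimal_expected_loss")
  curves <- purrr::map_dfr(plans, tidy)
  baseline <- NA_real_
  if (!is.null(baseline_r)) {
    check_number(baseline_r, "baseline_r", min = 0, allow_fractional = FALSE)
    baseline <- sum(purrr::map2_dbl(clinics$dist, clinics$costs,
                                    \(d, co) expected_loss(d, baseline_r, co)))
  }
  structure(
    list(plans = plan_tbl,
         curves = curves,
         total_expected_loss = sum(plan_tbl$optimal_expected_loss),
         baseline_r = baseline_r,
         baseline_loss = baseline),
    class = "portfolio_report"
  )
}

#' Row minima of a table of per-clinic expected-loss curves
#'
#' Given per-clinic expected-loss curves (one row per clinic and candidate
#' level), picks each clinic's least-loss overbooking level and sums the
#' minima into the portfolio total.  This is the entry point for curves
#' produced elsewhere (e.g. a published summary table); curves computed by
#' this package give the same answer through [optimize_portfolio()].
#'
#' @param loss_table Tibble with columns `clinic_id`, `overbooked`,
#'   `expected_loss`; every clinic needs at least one row.
#' @return List with `minima` (tibble: `clinic_id`, `optimal_r`,
#'   `expected_loss`, ties broken toward the smallest level) and `total`
#'   (sum of the minima, SAR).
#' @export
#' @examples
#' res <- summarize_row_minima(example_loss_curves())
#' res$total # 2337.74
summarize_row_minima <- function(loss_table) {
  check_columns(loss_table, c("clinic_id", "overbooked", "expected_loss"),
                "`loss_table`")
  if (nrow(loss_table) == 0L) {
    abort("`loss_table` has no rows.")
  }
  check_number(loss_table$expected_loss, "expected_loss")
  first_seen <- unique(loss_table$clinic_id)
  minima <- loss_table |>
    dplyr::group_by(.data$clinic_id) |>
    dplyr::arrange(.data$overbooked, .by_group = TRUE) |>
    dplyr::slice_min(.data$expected_loss, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("clinic_id", optimal_r = "overbooked",
                  expected_loss = "expected_loss") |>
    dplyr::arrange(match(.data$clinic_id, first_seen))
  list(minima = minima, total = sum(minima$expected_loss))
}

#' @export
print.portfolio_report <- function(x, ...) {
  cat(sprintf("<portfolio_report> %d clinics\n", nrow(x$plans)))
  cat(sprintf("  total expected loss at optima: %s\n",
              format_sar(x$total_expected_loss)))
  if (!is.na(x$baseline_loss)) {
    cat(sprintf("  baseline (R = %d everywhere): %s\n",
                x$baseline_r, format_sar(x$baseline_loss)))
  }
  print(x$plans, ...)
  invisible(x)
}

#' @export
tidy.portfolio_report <- function(x, ...) {
  x$curves
}

#' @export
glance.portfolio_report <- function(x, ...) {
  tibble(
    n_clinics = nrow(x$plans),
    total_expected_loss = x$total_expected_loss,
    baseline_loss = x$baseline_loss
  )
}

#' Plot per-clinic optimal overbooking levels and expected losses
#'
#' Bars give each clinic's optimal overbooking level; points and a line
#' give the expected loss at that optimum (secondary axis).
#'
#' @param object A `portfolio_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.portfolio_report <- function(object, ...) {
  plans <- object$plans |>
    dplyr::mutate(clinic_id = factor(.data$clinic_id,
                                     levels = .data$clinic_id))
  scale <- max(plans$optimal_expected_loss) / max(plans$optimal_r)
  ggplot2::ggplot(plans, ggplot2::aes(x = .data$clinic_id)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$optimal_r), fill = "steelblue",
                      alpha = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$optimal_expected_loss / scale,
                                    group = 1), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$optimal_expected_loss / scale),
                        colour = "firebrick") +
    ggplot2::scale_y_continuous(
      name = "optimal overbooking level R*",
      sec.axis = ggplot2::sec_axis(~ . * scale,
                                   name = "expected loss at R* (SAR)")
    ) +
    ggplot2::labs(x = "clinic", title = "Per-clinic overbooking strategy") +
    ggplot2::theme_minimal()
}
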