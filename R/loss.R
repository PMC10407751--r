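#' Cost schedule for the overbooking loss model
#'
#' Defines how a mismatch between realized no-shows S and the overbooking
#' level R is priced.  Three modes are supported because field practice and
#' the printed loss tables it produces differ from a fully general
#' accounting:
#'
#' \describe{
#'   \item{`table_symmetric`}{loss = `operation_cost * |S - R|`.  Every
#'     mismatched slot -- idle capacity when S > R, a bumped overbooked
#'     patient when R > S -- is priced at the per-slot operation cost.  This
#'     is the default and reproduces the published 14-clinic loss tables.}
#'   \item{`general_piecewise`}{loss = `idle_cost * max(S - R, 0) +
#'     overage_cost * max(R - S, 0)` -- the classical newsvendor loss with
#'     separate shortfall and overage unit costs.}
#'   \item{`literal_eq5`}{loss = `|(CF + OC) * S - (CF + VC) * R|` where CF
#'     is the consultation fee, OC the per-slot operation cost and VC the
#'     per-patient overbooking cost.  Provided for fidelity to the model
#'     objective as sometimes written with fees included; note it is not a
#'     separable shortfall/overage loss.}
#' }
#'
#' @param operation_cost Per-slot operation cost OC, SAR (default 35).
#' @param mode One of `"table_symmetric"`, `"general_piecewise"`,
#'   `"literal_eq5"`.
#' @param idle_cost SAR per unmatched no-show (shortfall side); defaults to
#'   `operation_cost`.
#' @param overage_cost SAR per bumped overbooked patient; defaults to
#'   `operation_cost`.
#' @param consultation_fee CF, SAR per visit (used by `literal_eq5`).
#' @param overbooking_cost VC, SAR per overbooked patient (used by
#'   `literal_eq5`).
#' @return An object of class `cost_schedule`.
#' @export
#' @examples
#' cost_schedule() # symmetric at SAR 35
#' cost_schedule(mode = "general_piecewise", idle_cost = 90, overage_cost = 10)
cost_schedule <- function(operation_cost = 35,
                          mode = c("table_symmetric", "general_piecewise",
                                   "literal_eq5"),
                          idle_cost = operation_cost,
                          overage_cost = operation_cost,
                          consultation_fee = NULL,
                          overbooking_cost = NULL) {
  mode <- match.arg(mode)
  check_number(operation_cost, "operation_cost", min = 0)
  check_number(idle_cost, "idle_cost", min = 0)
  check_number(overage_cost, "overage_cost", min = 0)
  if (mode == "literal_eq5") {
    if (is.null(consultation_fee) || is.null(overbooking_cost)) {
      abort("literal_eq5 mode needs `consultation_fee` and `overbooking_cost`.")
    }
    check_number(consultation_fee, "consultation_fee", min = 0)
    check_number(overbooking_cost, "overbooking_cost", min = 0)
  }
  if (mode == "table_symmetric") {
    idle_cost <- overage_cost <- operation_cost
  }
  if (idle_cost + overage_cost <= 0 && mode != "literal_eq5") {
    abort("At least one of `idle_cost`, `overage_cost` must be positive.")
  }
  structure(
    list(mode = mode, operation_cost = operation_cost,
         idle_cost = idle_cost, overage_cost = overage_cost,
         consultation_fee = consultation_fee,
         overbooking_cost = overbooking_cost),
    class = "cost_schedule"
  )
}

#' @export
print.cost_schedule <- function(x, ...) {
  cat(sprintf("<cost_schedule> mode = %s\n", x$mode))
  if (x$mode == "literal_eq5") {
    cat(sprintf("  CF = %s, OC = %s, VC = %s\n", x$consultation_fee,
                x$operation_cost, x$overbooking_cost))
  } else {
    cat(sprintf("  idle (shortfall) = %s SAR/slot, overage = %s SAR/patient\n",
                x$idle_cost, x$overage_cost))
  }
  invisible(x)
}

#' Monetary loss of one (no-shows, overbooked) outcome
#'
#' @param s Realized daily no-show count(s), >= 0.
#' @param r Overbooking level(s), >= 0.  `s` and `r` are recycled to a
#'   common length.
#' @param costs A [cost_schedule()].
#' @return Loss in SAR, vectorized.
#' @export
#' @examples
#' loss_cell(10, 1, cost_schedule()) # 315
loss_cell <- function(s, r, costs = cost_schedule()) {
  stopifnot(inherits(costs, "cost_schedule"))
  check_number(s, "s", min = 0)
  check_number(r, "r", min = 0)
  switch(costs$mode,
    table_symmetric = costs$operation_cost * abs(s - r),
    general_piecewise =
      costs$idle_cost * pmax(s - r, 0) + costs$overage_cost * pmax(r - s, 0),
    literal_eq5 =
      abs((costs$consultation_fee + costs$operation_cost) * s -
          (costs$consultation_fee + costs$overbooking_cost) * r)
  )
}

#' Build the overbooking loss table
#'
#' One cell per (realized no-shows S, overbooking level R) pair, priced by
#' [loss_cell()].  The diagonal S = R is zero in the symmetric mode:
#' overbooking exactly offsets the no-shows and no money is lost.
#'
#' @param support No-show counts (rows), nonnegative integers.
#' @param candidates Overbooking levels (columns), nonnegative integers.
#' @param costs A [cost_schedule()].
#' @return A tibble of class `loss_matrix` in long form with columns
#'   `no_shows`, `overbooked`, `loss`.  Use [loss_matrix_wide()] for the
#'   rows-by-columns layout.
#' @export
#' @examples
#' build_loss_matrix(1:10, 1:10, cost_schedule())
build_loss_matrix <- function(support, candidates, costs = cost_schedule()) {
  check_number(support, "support", min = 0, allow_fractional = FALSE)
  check_number(candidates, "candidates", min = 0, allow_fractional = FALSE)
  grid <- tidyr::expand_grid(no_shows = support, overbooked = candidates)
  out <- grid |>
    dplyr::mutate(loss = loss_cell(.data$no_shows, .data$overbooked, costs))
  structure(out, class = c("loss_matrix", class(out)))
}

#' Pivot a loss table to the rows = S, columns = R layout
#'
#' @param x A `loss_matrix` from [build_loss_matrix()].
#' @return Tibble with a `no_shows` column and one `r_<R>` column per
#'   overbooking level.
#' @export
loss_matrix_wide <- function(x) {
  check_columns(x, c("no_shows", "overbooked", "loss"), "`x`")
  x |>
    as_tibble() |>
    tidyr::pivot_wider(names_from = "overbooked", values_from = "loss",
                       names_prefix = "r_")
}

#' Expected loss of an overbooking level
#'
#' The no-show cost factor of level R: the probability-weighted sum of loss
#' cells over the no-show distribution, `sum_s P(s) * loss(s, R)`, at full
#' precision.
#'
#' @param dist A [noshow_distribution()].
#' @param r Overbooking level(s); vectorized.
#' @param costs A [cost_schedule()].
#' @return Expected loss in SAR, one value per element of `r`.
#' @export
#' @examples
#' d <- noshow_distribution(example_noshow_freq())
#' expected_loss(d, 6) # 35 * 185/88 = 73.58
expected_loss <- function(dist, r, costs = cost_schedule()) {
  stopifnot(inherits(dist, "noshow_distribution"))
  check_number(r, "r", min = 0)
  vapply(r, function(ri) sum(dist$pmf * loss_cell(dist$no_shows, ri, costs)),
         numeric(1))
}

#' Choose the overbooking level with least expected loss
#'
#' Evaluates [expected_loss()] at every candidate level and returns the
#' minimizer; ties are broken toward the smallest level (least
#' intervention).  For `general_piecewise` (and the symmetric special case)
#' the expected loss is discretely convex in R, and the optimum coincides
#' with the distribution quantile at the [critical_fractile()].
#'
#' @param dist A [noshow_distribution()].
#' @param costs A [cost_schedule()].
#' @param candidates Candidate overbooking levels; defaults to
#'   `0:max(support)`.
#' @param clinic_id Optional identifier carried into the result.
#' @return An object of class `overbooking_plan` with elements `clinic_id`,
#'   `curve` (tibble: `overbooked`, `expected_loss`), `optimal_r`,
#'   `optimal_expected_loss`, and `costs`.
#' @export
#' @examples
#' d <- noshow_distribution(example_noshow_freq())
#' plan <- optimize_overbooking(d, candidates = 1:10)
#' plan$optimal_r # 6
#' tidy(plan)
optimize_overbooking <- function(dist, costs = cost_schedule(),
                                 candidates = NULL, clinic_id = NA_character_) {
  stopifnot(inherits(dist, "noshow_distribution"))
  candidates <- candidates %||% seq(0L, max(dist$no_shows))
  if (length(candidates) == 0L) {
    abort("`candidates` must be a nonempty set of overbooking levels.")
  }
  check_number(candidates, "candidates", min = 0, allow_fractional = FALSE)
  candidates <- sort(unique(candidates))
  curve <- tibble(
    overbooked = candidates,
    expected_loss = expected_loss(dist, candidates, costs)
  )
  # ties break toward the smallest R; the relative tolerance keeps exact
  # flat regions (rational tie points) from being split by one-ulp noise
  lo <- min(curve$expected_loss)
  best <- which(curve$expected_loss <= lo + 1e-9 * max(lo, 1))[1]
  structure(
    list(clinic_id = clinic_id,
         curve = curve,
         optimal_r = curve$overbooked[best],
         optimal_expected_loss = curve$expected_loss[best],
         costs = costs),
    class = "overbooking_plan"
  )
}

#' @export
print.overbooking_plan <- function(x, ...) {
  id <- if (is.na(x$clinic_id)) "" else sprintf(" [clinic %s]", x$clinic_id)
  cat(sprintf("<overbooking_plan>%s\n", id))
  cat(sprintf("  candidates R = %s..%s (%d levels)\n",
              min(x$curve$overbooked), max(x$curve$overbooked),
              nrow(x$curve)))
  cat(sprintf("  optimal R* = %d, expected loss %s\n",
              x$optimal_r, format_sar(x$optimal_expected_loss)))
  invisible(x)
}

#' @export
tidy.overbooking_plan <- function(x, ...) {
  x$curve |>
    dplyr::mutate(clinic_id = x$clinic_id,
                  optimal = .data$overbooked == x$optimal_r,
                  .before = 1)
}

#' @export
glance.overbooking_plan <- function(x, ...) {
  tibble(
    clinic_id = x$clinic_id,
    n_candidates = nrow(x$curve),
    optimal_r = x$optimal_r,
    optimal_expected_loss = x$optimal_expected_loss
  )
}

#' Plot an expected-loss curve
#'
#' @param object An `overbooking_plan`.
#' @param ... Unused.
#' @return A ggplot object with the optimum highlighted.
#' @export
autoplot.overbooking_plan <- function(object, ...) {
  curve <- object$curve
  opt <- curve[curve$overbooked == object$optimal_r, ]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$overbooked,
                                      y = .data$expected_loss)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = opt, colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = curve$overbooked) +
    ggplot2::labs(x = "appointments overbooked (R)",
                  y = "expected loss (SAR)",
                  title = sprintf("Expected overbooking loss; R* = %d",
                                  object$optimal_r)) +
    ggplot2::theme_minimal()
}

#' Critical fractile of a cost schedule
#'
#' The newsvendor ratio `idle / (idle + overage)`: the overbooking level
#' minimizing expected piecewise-linear loss is the smallest level whose CDF
#' reaches this fractile.  With symmetric costs the fractile is 1/2 and the
#' rule picks the distribution median.  It balances the marginal cost of an
#' idle slot against that of a bumped patient; at the balance point the two
#' sides of the loss are equal in expectation.
#'
#' @param costs A [cost_schedule()] in `table_symmetric` or
#'   `general_piecewise` mode (the `literal_eq5` objective has no
#'   shortfall/overage decomposition and is rejected).
#' @return A probability in (0, 1).
#' @export
#' @examples
#' critical_fractile(cost_schedule()) # 0.5
#' critical_fractile(cost_schedule(mode = "general_piecewise",
#'                                 idle_cost = 90, overage_cost = 10)) # 0.9
critical_fractile <- function(costs) {
  stopifnot(inherits(costs, "cost_schedule"))
  if (costs$mode == "literal_eq5") {
    abort("The literal_eq5 loss has no critical fractile; use table_symmetric or general_piecewise.")
  }
  if (costs$idle_cost + costs$overage_cost <= 0) {
    abort("`idle_cost + overage_cost` must be positive.")
  }
  costs$idle_cost / (costs$idle_cost + costs$overage_cost)
}
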