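# Readers and writers for the CSV/JSON schemas.
# CSV dialect throughout: comma-separated, UTF-8, "." decimal separator,
# header row required; SAR amounts are plain decimals without symbols.

obk_schema_version <- "1"

#' Read a clinic-profile table
#'
#' Expects one row per clinic with columns `clinic_id`, `name`,
#' `n_doctors`, `n_nurses`, `consultations_per_hour`, `hours_per_shift`,
#' `consultation_fee_sar`, `operation_cost_per_slot_sar`,
#' `overbooking_cost_per_patient_sar`.  Capacity is recomputed from the
#' staffing columns; if the file carries its own `max_capacity` column it
#' must agree with the recomputed value.
#'
#' @param path Path to a CSV file.
#' @return Tibble of validated clinic profiles with `max_capacity`.
#' @export
read_clinics <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    clinic_id = readr::col_character(),
    name = readr::col_character(),
    .default = readr::col_double()
  ))
  required <- c("clinic_id", "name", "n_doctors", "n_nurses",
                "consultations_per_hour", "hours_per_shift",
                "consultation_fee_sar", "operation_cost_per_slot_sar",
                "overbooking_cost_per_patient_sar")
  check_columns(raw, required, sprintf("Clinic file '%s'", path))
  if (nrow(raw) == 0L) {
    abort(sprintf("Clinic file '%s' has no rows.", path))
  }
  for (col in setdiff(required, c("clinic_id", "name"))) {
    bad <- which(is.na(raw[[col]]) | raw[[col]] < 0)
    if (length(bad) > 0L) {
      abort(sprintf("Clinic file '%s': column %s has missing/negative value on row %d.",
                    path, col, bad[1]))
    }
  }
  if (anyDuplicated(raw$clinic_id) > 0L) {
    abort(sprintf("Clinic file '%s' has duplicate clinic_id values.", path))
  }
  out <- add_capacity(dplyr::select(raw, -dplyr::any_of("max_capacity")))
  if ("max_capacity" %in% names(raw)) {
    mism <- which(raw$max_capacity != out$max_capacity)
    if (length(mism) > 0L) {
      abort(sprintf(
        "Clinic file '%s': row %d declares max_capacity %s but staffing implies %s.",
        path, mism[1], raw$max_capacity[mism[1]], out$max_capacity[mism[1]]))
    }
  }
  out
}

#' Read a no-show frequency table
#'
#' Schema: `clinic_id`, `no_shows`, `frequency`.
#'
#' @param path Path to a CSV file.
#' @param clinic_id Optional: keep only this clinic's rows.
#' @return Tibble with columns `clinic_id`, `no_shows`, `frequency`.
#' @export
read_noshow_freq <- function(path, clinic_id = NULL) {
  out <- readr::read_csv(path, col_types = readr::cols(
    clinic_id = readr::col_character(),
    no_shows = readr::col_integer(),
    frequency = readr::col_integer()
  ))
  check_columns(out, c("clinic_id", "no_shows", "frequency"),
                sprintf("Frequency file '%s'", path))
  if (!is.null(clinic_id)) {
    out <- dplyr::filter(out, .data$clinic_id == !!as.character(clinic_id))
  }
  if (nrow(out) == 0L) {
    abort(sprintf("Frequency file '%s' has no usable rows.", path))
  }
  out
}

#' Read a per-day appointment log
#'
#' Schema: `date` (ISO-8601), `clinic_id`, `booked`, `shows`.
#'
#' @param path Path to a CSV file.
#' @return Tibble with a derived `no_shows` column.
#' @export
read_appointments <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(),
    clinic_id = readr::col_character(),
    booked = readr::col_integer(),
    shows = readr::col_integer()
  ))
  check_columns(out, c("date", "clinic_id", "booked", "shows"),
                sprintf("Appointment log '%s'", path))
  if (nrow(out) == 0L) {
    abort(sprintf("Appointment log '%s' is empty.", path))
  }
  bad <- which(out$shows > out$booked)
  if (length(bad) > 0L) {
    abort(sprintf("Appointment log '%s': shows > booked on row %d.",
                  path, bad[1]))
  }
  dplyr::mutate(out, no_shows = .data$booked - .data$shows)
}

#' Read annual cost line items
#'
#' Schema: `line_item`, `sar_per_year`.
#'
#' @param path Path to a CSV file.
#' @return Tibble of cost line items (validated by [aggregate_costs()]).
#' @export
read_cost_items <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    line_item = readr::col_character(),
    sar_per_year = readr::col_double()
  ))
  check_columns(out, c("line_item", "sar_per_year"),
                sprintf("Cost file '%s'", path))
  out
}

#' Loss-table report for one clinic
#'
#' Assembles the classic overbooking loss-table layout: one row per
#' no-show count with its probability and the loss under each candidate
#' overbooking level, plus a final `SCF` row holding the expected loss of
#' each column.  Cell values are full precision; `digits` rounds for
#' display.
#'
#' @param dist A [noshow_distribution()].
#' @param costs A [cost_schedule()].
#' @param candidates Overbooking levels (columns); default `1:max support`.
#' @param digits Rounding applied to probabilities and the SCF row
#'   (default 2, the usual report convention); `NULL` for full precision.
#' @return Tibble: `row` (no-show count as character, or `"SCF"`),
#'   `probability`, and one `r_<R>` column per candidate.
#' @export
#' @examples
#' d <- noshow_distribution(example_noshow_freq())
#' loss_table_report(d, cost_schedule(), 1:10)
loss_table_report <- function(dist, costs = cost_schedule(),
                              candidates = NULL, digits = 2) {
  stopifnot(inherits(dist, "noshow_distribution"))
  candidates <- candidates %||% seq(1L, max(dist$no_shows))
  body <- build_loss_matrix(dist$no_shows, candidates, costs) |>
    loss_matrix_wide() |>
    dplyr::mutate(probability = dist$pmf, .after = "no_shows")
  scf <- expected_loss(dist, candidates, costs)
  if (!is.null(digits)) {
    body$probability <- round(body$probability, digits)
    scf <- round(scf, digits)
  }
  scf_row <- tibble(no_shows = NA_integer_, probability = NA_real_)
  scf_row[paste0("r_", candidates)] <- as.list(scf)
  dplyr::bind_rows(body, scf_row) |>
    dplyr::mutate(row = dplyr::if_else(is.na(.data$no_shows), "SCF",
                                       as.character(.data$no_shows)),
                  .before = 1) |>
    dplyr::select(-"no_shows")
}

#' Write an overbooking plan or portfolio report
#'
#' `write_plan_json()` serializes a single clinic's plan;
#' `write_portfolio_json()` a multi-clinic report.
#' `write_portfolio_csv()` writes the summary-table layout: one row per
#' clinic, one column per overbooking level, plus the optimum flagged in
#' `optimal_r`/`optimal_expected_loss` columns.  JSON files carry a
#' `schema_version` field.
#'
#' @param plan An `overbooking_plan`.
#' @param report A `portfolio_report`.
#' @param path Output file path.
#' @param digits Display rounding for CSV (default 2); JSON is full
#'   precision.
#' @return The path, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "overbooking_plan"))
  jsonlite::write_json(
    list(schema_version = obk_schema_version,
         clinic_id = plan$clinic_id,
         mode = plan$costs$mode,
         candidates = plan$curve$overbooked,
         expected_losses = plan$curve$expected_loss,
         optimal_r = plan$optimal_r,
         optimal_expected_loss = plan$optimal_expected_loss),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
write_portfolio_json <- function(report, path) {
  stopifnot(inherits(report, "portfolio_report"))
  jsonlite::write_json(
    list(schema_version = obk_schema_version,
         plans = report$plans,
         total_expected_loss = report$total_expected_loss,
         baseline_r = report$baseline_r %||% NULL,
         baseline_loss = if (is.na(report$baseline_loss)) NULL else
           report$baseline_loss),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
write_portfolio_csv <- function(report, path, digits = 2) {
  stopifnot(inherits(report, "portfolio_report"))
  wide <- report$curves |>
    dplyr::mutate(expected_loss = round(.data$expected_loss, digits)) |>
    dplyr::select("clinic_id", "overbooked", "expected_loss") |>
    tidyr::pivot_wider(names_from = "overbooked",
                       values_from = "expected_loss", names_prefix = "r_") |>
    dplyr::left_join(
      dplyr::mutate(report$plans,
                    optimal_expected_loss = round(.data$optimal_expected_loss,
                                                  digits)),
      by = "clinic_id")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Write tables and logs in the package's CSV schemas
#'
#' @param x A tibble in one of the package schemas (appointment log,
#'   frequency table, per-day simulation outcomes, loss-table report).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}
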