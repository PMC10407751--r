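#' Daily consultation capacity of a clinic
#'
#' A clinic's daily capacity is the sum over its physicians of
#' (consultations per hour) x (working hours per shift).  No rounding is
#' applied: if a physician's rate or shift length is fractional the capacity
#' may be fractional too, so callers scheduling whole 30-minute slots should
#' supply integer-valued products.
#'
#' @param physicians Data frame with one row per physician and columns
#'   `consultations_per_hour` and `hours_per_shift`, both nonnegative.
#'   An empty data frame (zero physicians) yields capacity 0.
#' @return A single number: patients per day.
#' @export
#' @examples
#' staff <- tibble::tibble(consultations_per_hour = rep(2, 3),
#'                         hours_per_shift = rep(6, 3))
#' clinic_capacity(staff) # 36
clinic_capacity <- function(physicians) {
  check_columns(physicians, c("consultations_per_hour", "hours_per_shift"),
                "`physicians`")
  if (nrow(physicians) == 0L) {
    return(0)
  }
  check_number(physicians$consultations_per_hour, "consultations_per_hour",
               min = 0)
  check_number(physicians$hours_per_shift, "hours_per_shift", min = 0)
  sum(physicians$consultations_per_hour * physicians$hours_per_shift)
}

#' Expand clinic rows into a per-physician staffing table
#'
#' Clinic tables record a physician headcount and a common per-physician
#' rate/shift; this expands them to the one-row-per-physician layout
#' [clinic_capacity()] expects.
#'
#' @param clinics Data frame with columns `clinic_id`, `n_doctors`,
#'   `consultations_per_hour`, `hours_per_shift`.
#' @return Tibble with one row per physician.
#' @export
physician_shifts <- function(clinics) {
  check_columns(clinics, c("clinic_id", "n_doctors", "consultations_per_hour",
                           "hours_per_shift"), "`clinics`")
  check_number(clinics$n_doctors, "n_doctors", min = 0,
               allow_fractional = FALSE)
  clinics |>
    dplyr::select("clinic_id", "n_doctors", "consultations_per_hour",
                  "hours_per_shift") |>
    tidyr::uncount(.data$n_doctors) |>
    as_tibble()
}

#' Recompute per-clinic capacity from staffing columns
#'
#' @param clinics Data frame with columns `clinic_id`, `n_doctors`,
#'   `consultations_per_hour`, `hours_per_shift`.
#' @return The input as a tibble with a `max_capacity` column
#'   (patients/day) appended or replaced.
#' @export
#' @examples
#' add_capacity(example_clinics())
add_capacity <- function(clinics) {
  shifts <- physician_shifts(clinics)
  caps <- shifts |>
    dplyr::group_by(.data$clinic_id) |>
    dplyr::summarise(
      max_capacity = sum(.data$consultations_per_hour * .data$hours_per_shift),
      .groups = "drop"
    )
  clinics |>
    as_tibble() |>
    dplyr::select(-dplyr::any_of("max_capacity")) |>
    dplyr::left_join(caps, by = "clinic_id") |>
    dplyr::mutate(max_capacity = dplyr::coalesce(.data$max_capacity, 0))
}

# Canonical cost line items of the annual operating budget.
cost_line_item_names <- c(
  "utilities", "government_fees", "space_rent",
  "doctor_salaries", "nurse_salaries", "admin_salaries"
)

#' Total annual operating cost from line items
#'
#' Sums the six canonical budget line items (utilities, government fees,
#' space rent, and doctor/nurse/administrative salaries).  All six must be
#' present exactly once and be nonnegative; the sum is exact for whole-riyal
#' inputs.
#'
#' @param items Data frame with columns `line_item` and `sar_per_year`.
#' @return Total cost in SAR per year (a single number).
#' @export
#' @examples
#' aggregate_costs(example_cost_items()) # 14883519
aggregate_costs <- function(items) {
  check_columns(items, c("line_item", "sar_per_year"), "`items`")
  missing <- setdiff(cost_line_item_names, items$line_item)
  if (length(missing) > 0L) {
    abort(sprintf("Missing cost line item(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  dup <- items$line_item[duplicated(items$line_item)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicated cost line item(s): %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  extra <- setdiff(items$line_item, cost_line_item_names)
  if (length(extra) > 0L) {
    abort(sprintf("Unknown cost line item(s): %s.",
                  paste(extra, collapse = ", ")))
  }
  check_number(items$sar_per_year, "sar_per_year", min = 0)
  sum(items$sar_per_year)
}

#' Allocate an annual cost to a 30-minute appointment slot
#'
#' Divides a total annual cost evenly over `operating_days_per_year` days of
#' `slots_per_day` appointment slots each.  This is a convenience allocation
#' helper: clinics that already know their per-slot operating cost should
#' supply it directly in the cost schedule rather than derive it here, since
#' even allocation over slots is only one of several defensible accounting
#' conventions.
#'
#' @param total_annual Total cost, SAR per year.
#' @param operating_days_per_year Days the clinics operate per year (> 0).
#' @param slots_per_day Number of 30-minute slots per operating day (> 0).
#' @return Cost per slot in SAR.
#' @export
#' @examples
#' per_slot_cost(1000, 10, 10) # 10
per_slot_cost <- function(total_annual, operating_days_per_year,
                          slots_per_day) {
  check_number(total_annual, "total_annual", min = 0)
  check_number(operating_days_per_year, "operating_days_per_year")
  check_number(slots_per_day, "slots_per_day")
  if (operating_days_per_year <= 0 || slots_per_day <= 0) {
    abort("`operating_days_per_year` and `slots_per_day` must be > 0.")
  }
  total_annual / (operating_days_per_year * slots_per_day)
}
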