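#' Generate a synthetic per-day appointment log
#'
#' Emulates the appointment history a clinic would tally into a no-show
#' frequency table.  Three generating models are available:
#'
#' \describe{
#'   \item{`fixed_prob`}{every booked patient independently shows with
#'     probability `show_prob`; daily no-shows are
#'     Binomial(booked, 1 - show_prob).}
#'   \item{`beta_binomial`}{the daily show probability is itself drawn from
#'     Beta(`alpha`, `beta`), giving the overdispersion real no-show counts
#'     exhibit relative to a plain binomial.}
#'   \item{`empirical`}{daily no-show counts are resampled directly from a
#'     supplied [noshow_distribution()] -- closest to working from an
#'     observed frequency table.}
#' }
#'
#' @param n_days Number of clinic days to generate (>= 1).
#' @param booked_per_day Appointments booked each day.
#' @param show_model One of `"fixed_prob"`, `"beta_binomial"`,
#'   `"empirical"`.
#' @param show_prob Per-patient show probability (fixed_prob).
#' @param alpha,beta Beta parameters of the daily show probability
#'   (beta_binomial), both > 0.
#' @param dist A [noshow_distribution()] to resample (empirical); its
#'   support must not exceed `booked_per_day`.
#' @param seed Optional integer for reproducibility.
#' @param clinic_id Identifier written into every record.
#' @param start_date First date of the log (default 2026-01-01); one record
#'   per consecutive day.
#' @return Tibble with columns `date`, `clinic_id`, `booked`, `shows`,
#'   `no_shows` -- the appointment-log schema consumed by
#'   [freq_from_log()].
#' @export
#' @examples
#' log <- generate_log(n_days = 88, booked_per_day = 36,
#'                     show_model = "empirical",
#'                     dist = noshow_distribution(example_noshow_freq()),
#'                     seed = 7)
#' freq_from_log(log)
generate_log <- function(n_days, booked_per_day,
                         show_model = c("fixed_prob", "beta_binomial",
                                        "empirical"),
                         show_prob = NULL, alpha = NULL, beta = NULL,
                         dist = NULL, seed = NULL, clinic_id = "1",
                         start_date = as.Date("2026-01-01")) {
  show_model <- match.arg(show_model)
  check_number(n_days, "n_days", min = 1, allow_fractional = FALSE)
  check_number(booked_per_day, "booked_per_day", min = 0,
               allow_fractional = FALSE)
  if (!is.null(seed)) {
    set.seed(seed)
  }
  no_shows <- switch(show_model,
    fixed_prob = {
      if (is.null(show_prob)) abort("fixed_prob model needs `show_prob`.")
      check_number(show_prob, "show_prob", min = 0)
      if (show_prob > 1) abort("`show_prob` must be in [0, 1].")
      rbinom(n_days, booked_per_day, 1 - show_prob)
    },
    beta_binomial = {
      if (is.null(alpha) || is.null(beta)) {
        abort("beta_binomial model needs `alpha` and `beta`.")
      }
      if (alpha <= 0 || beta <= 0) abort("`alpha` and `beta` must be > 0.")
      p_show <- rbeta(n_days, alpha, beta)
      rbinom(n_days, booked_per_day, 1 - p_show)
    },
    empirical = {
      if (!inherits(dist, "noshow_distribution")) {
        abort("empirical model needs `dist`, a noshow_distribution.")
      }
      if (max(dist$no_shows) > booked_per_day) {
        abort("`booked_per_day` is smaller than the distribution's support.")
      }
      dist$no_shows[sample.int(nrow(dist), n_days, replace = TRUE,
                               prob = dist$pmf)]
    }
  )
  tibble(
    date = start_date + seq_len(n_days) - 1L,
    clinic_id = clinic_id,
    booked = as.integer(booked_per_day),
    shows = as.integer(booked_per_day - no_shows),
    no_shows = as.integer(no_shows)
  )
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "overbookr")
  if (path == "") {
    abort(sprintf("Bundled fixture %s not found; is overbookr installed?",
                  file))
  }
  path
}

#' Bundled 14-clinic case-study tables
#'
#' Operational data for a 14-department outpatient medical centre
#' (endocrinology through pulmonology): staffing, daily capacity,
#' consultation fees and per-patient costs, the centre's annual cost line
#' items, one clinic's observed no-show frequency table (88 days,
#' counts 1..10), and the published per-clinic expected-loss curves over
#' overbooking levels 1..10.  Each clinic's capacity equals
#' 12 consultations per physician per day, encoded as 2 consultations/hour
#' over a 6-hour shift.
#'
#' @return
#' `example_clinics()`: tibble of 14 clinic profiles with `max_capacity`
#' recomputed from staffing.
#' `example_cost_items()`: tibble of the six annual cost line items.
#' `example_noshow_freq()`: tibble `no_shows`/`frequency` for clinic 1.
#' `example_loss_curves()`: long tibble `clinic_id`/`overbooked`/
#' `expected_loss` of the published curves (clinic_id as character).
#' @export
#' @examples
#' example_clinics()
#' aggregate_costs(example_cost_items())
example_clinics <- function() {
  readr::read_csv(extdata_path("clinics.csv"),
                  col_types = readr::cols(
                    clinic_id = readr::col_character(),
                    name = readr::col_character(),
                    .default = readr::col_double()
                  )) |>
    add_capacity()
}

#' @rdname example_clinics
#' @export
example_cost_items <- function() {
  readr::read_csv(extdata_path("costs.csv"),
                  col_types = readr::cols(
                    line_item = readr::col_character(),
                    sar_per_year = readr::col_double()
                  ))
}

#' @rdname example_clinics
#' @export
example_noshow_freq <- function() {
  readr::read_csv(extdata_path("noshow_freq.csv"),
                  col_types = readr::cols(
                    clinic_id = readr::col_character(),
                    no_shows = readr::col_integer(),
                    frequency = readr::col_integer()
                  )) |>
    dplyr::filter(.data$clinic_id == "1") |>
    dplyr::select("no_shows", "frequency")
}

#' @rdname example_clinics
#' @export
example_loss_curves <- function() {
  readr::read_csv(extdata_path("expected_loss_curves.csv"),
                  col_types = readr::cols(
                    clinic_id = readr::col_character(),
                    overbooked = readr::col_integer(),
                    expected_loss = readr::col_double()
                  ))
}
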