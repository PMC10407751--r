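#' Patient-flow timeline parameters
#'
#' Timing of one ideal clinic visit: patients arrive a few minutes before
#' the appointment, wait for check-in, are checked in, and see the
#' physician; the whole visit is planned to fit a fixed total.  The
#' consultation itself takes whatever remains of `total_visit` after the
#' arrival lead, the check-in service and the minimum check-in wait, so a
#' visit meets `total_visit` exactly when the wait is at its minimum and
#' exceeds it only by the extra wait.
#'
#' @param arrival_lead Minutes patients arrive before the appointment
#'   (default 5).
#' @param checkin_wait Length-2 numeric, min and max check-in waiting time
#'   in minutes (default `c(5, 10)`).
#' @param checkin_service Minutes the check-in itself takes (default 5).
#' @param total_visit Planned total visit length in minutes (default 30,
#'   one appointment slot).
#' @return An object of class `flow_timeline`.
#' @export
#' @examples
#' flow_timeline()
flow_timeline <- function(arrival_lead = 5, checkin_wait = c(5, 10),
                          checkin_service = 5, total_visit = 30) {
  check_number(arrival_lead, "arrival_lead", min = 0)
  check_number(checkin_service, "checkin_service", min = 0)
  check_number(total_visit, "total_visit", min = 0)
  if (length(checkin_wait) != 2L || anyNA(checkin_wait) ||
      any(checkin_wait < 0) || checkin_wait[1] > checkin_wait[2]) {
    abort("`checkin_wait` must be c(min, max) with 0 <= min <= max.")
  }
  consultation <- total_visit - arrival_lead - checkin_service -
    checkin_wait[1]
  if (consultation < 0) {
    abort("Timeline components exceed `total_visit` even at minimum wait.")
  }
  structure(
    list(arrival_lead = arrival_lead, checkin_wait = checkin_wait,
         checkin_service = checkin_service, total_visit = total_visit,
         consultation = consultation),
    class = "flow_timeline"
  )
}

#' Monte-Carlo simulation of clinic days under an overbooking level
#'
#' Draws the daily no-show count independently from the empirical
#' distribution, prices each day with [loss_cell()], and summarizes the
#' mean realized loss with its standard error.  Used to validate that the
#' analytic [expected_loss()] is what a clinic would actually average over
#' many days.
#'
#' @param dist A [noshow_distribution()].
#' @param r Overbooking level, >= 0.
#' @param costs A [cost_schedule()].
#' @param n_days Number of days to simulate (>= 1).
#' @param seed Optional integer; when given the run is reproducible.
#' @return An object of class `noshow_simulation`: a tibble with one row
#'   per day (`day`, `no_shows`, `loss`, `idle_slots`, `bumped_patients`)
#'   and attributes `mean_loss`, `se_loss`, `r`, `seed`.
#' @export
#' @examples
#' d <- noshow_distribution(example_noshow_freq())
#' sim <- simulate_days(d, r = 6, n_days = 1000, seed = 42)
#' glance(sim)
simulate_days <- function(dist, r, costs = cost_schedule(), n_days,
                          seed = NULL) {
  stopifnot(inherits(dist, "noshow_distribution"))
  check_number(r, "r", min = 0, allow_fractional = FALSE)
  check_number(n_days, "n_days", min = 1, allow_fractional = FALSE)
  if (!is.null(seed)) {
    check_number(seed, "seed")
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  # index-based draw: sample(x, ...) would misread a length-1 support
  draws <- dist$no_shows[sample.int(nrow(dist), size = n_days,
                                    replace = TRUE, prob = dist$pmf)]
  losses <- loss_cell(draws, r, costs)
  out <- tibble(
    day = seq_len(n_days),
    no_shows = draws,
    loss = losses,
    idle_slots = pmax(draws - r, 0),
    bumped_patients = pmax(r - draws, 0)
  )
  structure(out,
            mean_loss = mean(losses),
            se_loss = stats::sd(losses) / sqrt(n_days),
            r = r, seed = seed,
            class = c("noshow_simulation", class(out)))
}

#' @export
glance.noshow_simulation <- function(x, ...) {
  tibble(
    n_days = nrow(x),
    r = attr(x, "r"),
    mean_loss = attr(x, "mean_loss"),
    se_loss = attr(x, "se_loss"),
    mean_no_shows = mean(x$no_shows),
    seed = attr(x, "seed") %||% NA_integer_
  )
}

#' Find the empirically best overbooking level by simulation
#'
#' Simulates every candidate level with a common seed (common random
#' numbers, so all levels face the same no-show draws) and returns the
#' level with least mean realized loss.
#'
#' @inheritParams simulate_days
#' @param candidates Candidate overbooking levels.
#' @return Tibble with `overbooked`, `mean_loss`, `se_loss`, sorted by
#'   level, with the attribute `best_r` (argmin, ties to the smallest).
#' @export
simulate_argmin <- function(dist, candidates, costs = cost_schedule(),
                            n_days, seed = NULL) {
  check_number(candidates, "candidates", min = 0, allow_fractional = FALSE)
  candidates <- sort(unique(candidates))
  res <- purrr::map_dfr(candidates, function(r) {
    glance(simulate_days(dist, r, costs, n_days, seed = seed))[
      , c("r", "mean_loss", "se_loss")]
  })
  res <- dplyr::rename(res, overbooked = "r")
  structure(res, best_r = res$overbooked[which.min(res$mean_loss)],
            class = class(res))
}

#' Simulate per-patient visit timing
#'
#' Draws each patient's check-in wait uniformly on the timeline's range
#' (the least-assumption distribution given only bounds) and assembles the
#' realized visit duration from the timeline components.
#'
#' @param timeline A [flow_timeline()].
#' @param n_patients Number of patients to simulate (>= 1).
#' @param seed Optional integer for reproducibility.
#' @return Tibble with one row per patient: `patient`, `arrival_lead`,
#'   `checkin_wait`, `checkin_service`, `consultation`, `total_time`
#'   (minutes).
#' @export
#' @examples
#' flow <- simulate_patient_flow(flow_timeline(), 100, seed = 1)
#' summary(flow$checkin_wait) # within [5, 10]
simulate_patient_flow <- function(timeline = flow_timeline(), n_patients,
                                  seed = NULL) {
  stopifnot(inherits(timeline, "flow_timeline"))
  check_number(n_patients, "n_patients", min = 1, allow_fractional = FALSE)
  if (!is.null(seed)) {
    set.seed(seed)
  }
  wait <- runif(n_patients, timeline$checkin_wait[1],
                timeline$checkin_wait[2])
  tibble(
    patient = seq_len(n_patients),
    arrival_lead = timeline$arrival_lead,
    checkin_wait = wait,
    checkin_service = timeline$checkin_service,
    consultation = timeline$consultation,
    total_time = timeline$arrival_lead + wait + timeline$checkin_service +
      timeline$consultation
  )
}
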