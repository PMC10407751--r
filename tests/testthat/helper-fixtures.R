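# Fixture builders shared across the suite.  All randomness goes through an
# explicit seed so reruns are bit-identical.

# Observed 88-day no-show history of the endocrinology clinic (counts 1..10).
clinic1_freq <- function() {
  tibble::tibble(no_shows = 1:10,
                 frequency = c(10L, 6L, 7L, 13L, 3L, 17L, 14L, 10L, 5L, 3L))
}

clinic1_dist <- function() noshow_distribution(clinic1_freq())

# Random dense frequency table on support starting at 0 or a small offset.
random_freq_table <- function(max_count = 10, min_count = 0) {
  support <- min_count:max_count
  freq <- rpois(length(support), lambda = 3)
  if (sum(freq) == 0) freq[1] <- 1L
  tibble::tibble(no_shows = support, frequency = as.integer(freq))
}

random_cost_general <- function() {
  cost_schedule(mode = "general_piecewise",
                idle_cost = sample(1:100, 1),
                overage_cost = sample(1:100, 1))
}

# Independent expected-loss oracle: plain base-R sum over the frequency
# table, bypassing the noshow_distribution/loss_cell machinery.
expected_loss_by_enumeration <- function(freq, r, idle, overage) {
  s <- freq$no_shows
  w <- freq$frequency / sum(freq$frequency)
  sum(w * (idle * pmax(s - r, 0) + overage * pmax(r - s, 0)))
}
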