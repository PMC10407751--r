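---
title: "The overbooking cost-minimization model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The overbooking cost-minimization model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overbookr)
library(dplyr)
```

## The decision problem

An outpatient clinic books up to its daily capacity, but some booked
patients fail to attend.  Each unmatched no-show leaves a 30-minute slot --
and the money that slot costs to run -- idle.  Overbooking `R` extra
reservations hedges against the no-shows `S`, but on days when fewer than
`R` patients fail to show, the surplus overbooked patients cannot be served
and must be re-referred, which also costs money.  The model chooses `R` to
minimize the expected monetary loss from the mismatch between `R` and the
random `S`.

Writing `L(s, r)` for the loss on a day with `s` no-shows under level `r`,
the objective is

$$R^* = \arg\min_r \; \mathbb{E}\,[L(S, r)] = \arg\min_r \sum_s P(S = s)\, L(s, r),$$

with `P` the clinic's empirical no-show distribution.  This is a discrete
newsvendor problem: for any piecewise-linear loss with shortfall unit cost
$c_u$ (an idle slot) and overage unit cost $c_o$ (a bumped patient), the
minimizer is the smallest `r` whose CDF reaches the *critical fractile*
$c_u / (c_u + c_o)$.  With symmetric costs the fractile is 1/2 and the
optimal level is the median number of daily no-shows.  The package always
optimizes by brute-force evaluation of the whole curve (the candidate sets
are tiny), and uses the fractile rule as an independent oracle in its test
suite.

## Estimating the no-show distribution

`noshow_distribution()` turns an observed frequency table -- "s no-shows
occurred on F_s of n days" -- into an empirical PMF `F_s / n` and its
running-sum CDF.  Two numerical choices matter:

* **Full precision.**  Probabilities are kept as exact fractions of `n`;
  the conventional 2-decimal rounding is applied only when formatting
  reports.  Published tables of this kind are often internally inconsistent
  precisely because they round before multiplying; working in fractions
  avoids propagating those inconsistencies.
* **Dense support.**  The support is filled in over the observed
  minimum..maximum, so an interior count never seen in the sample carries
  probability zero.  Loss curves are then evaluable at every candidate
  level.  Zero no-show days are allowed even though historical tables may
  start at 1; real logs contain them.

`freq_from_log()` tallies a per-day appointment log (booked minus shows)
into the same frequency form, and `noshow_quantile()` implements the
left-continuous discrete quantile used by the fractile rule.  Quantile
look-ups guard against one-ulp undershoot of the floating running sum with
a relative tolerance of 1e-9; without it an exact rational tie point could
be pushed one support value up.

## Pricing the mismatch

`cost_schedule()` supports three loss modes because field accounting and
fully general accounting differ:

* `table_symmetric` (default): every mismatched slot costs the per-slot
  operation cost OC, i.e. `L = OC * |S - R|`.  This prices an idle slot
  and a bumped patient identically and is the convention behind the
  published loss tables the package ships; with OC = 35 SAR it reproduces
  them cell-exactly.
* `general_piecewise`: separate unit costs for idle slots and bumped
  patients, `L = c_u max(S-R, 0) + c_o max(R-S, 0)` -- the classical
  newsvendor loss.  Use this when re-referring a patient genuinely costs
  more (or less) than an idle slot.
* `literal_eq5`: `L = |(CF + OC) S - (CF + VC) R|`, the objective as
  sometimes written with the consultation fee CF and per-patient
  overbooking cost VC included.  It is kept for fidelity; note it is not
  separable in shortfall/overage, so `critical_fractile()` rejects it and
  discrete convexity of its expected loss is not guaranteed.

The balance equation `(CF+OC) S = (CF+VC) R` occasionally written as a
"constraint" of this model is unsatisfiable for a random `S` and is not
enforced; it simply describes the point where the two sides of the loss
balance, which is what the critical fractile generalizes.

Ties in the minimum are broken toward the smallest `R` (least
intervention), with a 1e-9 relative tolerance so that exactly flat regions
of the curve -- which arise at rational tie points -- are not split by
floating-point noise.  Candidate levels default to `0:max(support)`;
published analyses often use `1:max(support)`, which callers can pass
explicitly.

## Parameters and units

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `operation_cost` (OC) | cost of running one 30-min slot | SAR | 35 |
| `idle_cost` / `overage_cost` | unit shortfall / overage cost | SAR | = OC |
| `consultation_fee` (CF) | fee per visit | SAR | clinic-specific |
| `overbooking_cost` (VC) | cost per bumped patient | SAR | clinic-specific |
| `candidates` | levels R evaluated | patients | 0..max support |

The bundled case study (`example_clinics()`) describes a 14-department
outpatient centre in which every clinic serves 12 consultations per
physician per day (encoded as 2/hour over a 6-hour shift -- the
decomposition is a convention; only the product is observable in such
tables), a uniform OC of 35 SAR derived by allocating the centre's
SAR 14,883,519 annual cost to 30-minute slots, and clinic-specific fees
and overbooking costs.  `per_slot_cost()` performs the even allocation
`total / (days x slots)`; it is a convenience, not an endorsement -- an
allocation of roughly 1165 slots/day over 365 days reproduces the
conventional 35, but clinics that know their true per-slot cost should
supply it directly.

## Portfolio aggregation

Clinics are optimized independently -- no shared physicians, rooms or
budget -- so the portfolio optimum is the sum of per-clinic optima.
`optimize_portfolio()` recomputes curves from distributions;
`summarize_row_minima()` takes already-computed curves (e.g. a published
summary table) and picks row minima.  The two entry points agree by
construction, which the suite asserts.  On the bundled 14-clinic curves
the row minima total SAR 2,337.74.

## Monte-Carlo validation and the flow timeline

`simulate_days()` draws daily no-show counts i.i.d. from the empirical
distribution and prices each day with the same loss cells, reporting the
mean realized loss with a standard error.  The law of large numbers brings
the mean within 3 SE of the analytic expectation at 1e5 days, which is the
problem size the test suite and the acceptance script both use (about a
second of work).  Day-of-week and seasonal structure are deliberately out
of scope: the model treats the no-show distribution as static, so the
simulator does too.

The visit timeline (`flow_timeline()`) captures the ideal intake flow:
arrive 5 minutes early, wait 5-10 minutes for check-in, 5 minutes of
check-in, and a visit planned to total 30 minutes.  Only the wait's bounds
are given, so it is modelled uniform on its range -- the least-assumption
choice on a stated interval.  The components do not pin down the
consultation length; the package defines it as
`total_visit - arrival_lead - checkin_service - min(checkin_wait)`
(15 minutes at defaults), so a visit meets the 30-minute total exactly at
the minimum wait and exceeds it only by the extra wait.  The flow
simulator is diagnostic; waiting times do not enter the optimization,
which is driven by costs alone.

## The synthetic generator

`generate_log()` emulates the appointment history a clinic would tally:

* `fixed_prob` -- every booked patient shows independently with
  probability `show_prob`; daily no-shows are binomial.
* `beta_binomial` -- the daily show probability is drawn from a Beta
  distribution, producing the overdispersion real no-show counts show
  relative to a binomial (day-level shocks such as weather affect all
  patients at once).
* `empirical` -- counts resampled from a supplied distribution, closest
  to working directly from an observed frequency table and the default
  choice for round-trip testing.

What passing the round-trip tests shows is that estimation inverts
generation under the model's own assumptions (i.i.d. days, a static
distribution); it does not show that real clinic data satisfy those
assumptions.  Covariate-driven no-show prediction per patient is a
different problem and out of scope.

## Worked example

```{r example}
dist <- noshow_distribution(example_noshow_freq())
glance(dist)

plan <- optimize_overbooking(dist, cost_schedule(), candidates = 1:10)
plan
tidy(plan)

res <- summarize_row_minima(example_loss_curves())
res$total
```

## Known limitations

* The empirical PMF is used as-is: no smoothing, no parametric fit, no
  uncertainty on the estimated optimum.  With short histories (the bundled
  clinic has 88 days) the optimum can be sensitive to a handful of days.
* Static and single-period: no re-optimization as bookings arrive, no
  patient classes, no revenue objective -- only expected-cost
  minimization.
* The symmetric default prices idle capacity and bumped patients
  identically; where re-referral damages goodwill, `general_piecewise`
  with a larger overage cost is the better model, and the optimum moves
  down the CDF accordingly.
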