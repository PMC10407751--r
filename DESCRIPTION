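Package: overbookr
Title: Overbooking Cost Minimization for Outpatient Clinics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing how many appointments an outpatient clinic
    should overbook to hedge against patient no-shows. Estimates the empirical
    discrete distribution of daily no-show counts from frequency tables or
    appointment logs, builds a monetary overbooking loss table, minimizes the
    probability-weighted expected loss over candidate overbooking levels
    (a discrete newsvendor problem, with a closed-form critical-fractile
    oracle), aggregates per-clinic optima into a portfolio report, and
    validates the analytic expected loss by seeded Monte-Carlo simulation of
    clinic days. Ships a 14-clinic outpatient case-study fixture and a
    synthetic appointment-log generator. All tabular inputs and outputs are
    data frames; results carry tidy() and glance() methods and ggplot2
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
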