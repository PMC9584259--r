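Package: fairbook
Title: Fair Predictive Overbooking for Outpatient Appointment Scheduling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying racial and socio-economic fairness in
    predictive-overbooking appointment scheduling. The package decouples the
    prediction stage (per-patient show-probability models fit under
    configurable feature regimes) from the schedule-optimization stage
    (slot-assignment search under a traditional cost-minimizing objective,
    min-max group-fair and min-max individual-fair objectives, and optional
    quota constraints on desirable slots). It provides an exact deterministic
    clinic-day recursion, exact and Monte-Carlo expected wait/idle/overtime
    evaluation, wait-time disparity and statistical-parity metrics, a
    synthetic clinic-population generator in which socio-economic features
    correlate with a binary group label, and a benchmark harness comparing
    scheduling methods end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
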