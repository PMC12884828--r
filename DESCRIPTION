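Package: emainertia
Title: Within-Day and Overnight Affective Inertia from Experience-Sampling Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for separating within-day and overnight affective inertia in
    intensive longitudinal (experience-sampling) data. Implements a Bayesian
    multilevel AR(1) model in which the lag-1 autoregression of momentary
    affect is split into a within-day and an overnight coefficient via dummy
    coding, estimated with a blocked Gibbs sampler. Posterior-derived
    contrasts compare the observed overnight autoregression against
    exponential-decay extrapolations of the within-day autoregression, and a
    rule-based classifier labels the overnight process as continuing,
    pausing, stopping, or different. Includes a synthetic data generator
    emulating a measurement-burst design with semi-random beep schedules,
    preprocessing utilities (composites, time in bed, adjacent-beep lags,
    interval filters, within/between decomposition), moderation models for
    momentary and trait covariates, multilevel composite reliability
    (McDonald's omega), and variance-explained summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
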