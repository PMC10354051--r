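Package: stopsignal
Title: Simulation and Hierarchical Bayesian Modelling of Stop-Signal Task Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for trial-level stop-signal task data built around the
    independent horse-race model with ex-Gaussian finishing times and
    trigger failures. Simulates staircase-tracked sessions and hierarchical
    cohorts from known parameters, applies the standard data-reduction
    screens (race-assumption check, responding-rate bounds, Tukey accuracy
    fences, anticipatory-response removal), estimates stop-signal reaction
    times nonparametrically by the integration method with replacement of
    omissions, and fits the trigger-failure race model ("BEESTS" with
    trigger failures) by hierarchical Bayesian MCMC. Includes convergence
    diagnostics, posterior summaries with credible intervals, pairwise
    Bayesian p-values for condition comparison, posterior predictive
    checks, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
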