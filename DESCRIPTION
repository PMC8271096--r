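Package: parcelfit
Title: Personalized Whole-Brain Oscillator Models Across Parcellations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives personalized delayed Kuramoto phase-oscillator and
    Hopf limit-cycle network models from parcellation-level structural
    connectomes and BOLD time series, fits them to empirical functional
    and structural connectivity by exhaustive grid search over the global
    delay and coupling strength, and quantifies inter-subject and
    inter-parcellation variability of the goodness-of-fit with
    correlation, signed-rank, and multiple-regression analyses. Includes
    a synthetic-cohort generator with hierarchical parcellations and
    known ground-truth dynamics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
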