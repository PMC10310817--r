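Package: spherofact
Title: Competition and Facilitation Between Drug-Sensitive and Resistant
    Cancer Lineages in Spheroid Coculture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies ecological interactions between drug-sensitive and
    drug-resistant ER+ breast cancer lineages grown as 3D spheroids under
    CDK4/6 inhibition. Provides cell-count calibration from spheroid area
    and two-channel fluorescence, the six-step FACT algorithm (logistic and
    Lotka-Volterra fits yielding per-day facilitation scores against a
    multiplicative null model), Michaelis-Menten estradiol production/uptake
    models with detection-limit censoring and profile-likelihood intervals,
    a stage-structured consumer-resource model of facilitation with
    Hamiltonian Monte Carlo inference and WAIC model comparison, and
    synthetic-data generators that emulate the full dose-panel experimental
    design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
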