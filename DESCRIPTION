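Package: horizonDDM
Title: Drift-Diffusion Modelling of Explore-Exploit Decisions in the Horizon Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing explore-exploit behaviour in the Horizon Task,
    a two-armed bandit game with forced-information trials and a horizon
    manipulation. Implements a trial-linked drift-diffusion model of choices
    and response times on the first free-choice trial, including fast Wiener
    first-passage-time densities, maximum-likelihood fitting with yoked model
    variants, the logistic bias-noise-bonus choice model, a response-time
    regression, a synthetic cohort generator with young-like and old-like
    parameter regimes, parameter recovery, posterior predictive checks,
    leave-one-out model comparison, and the decision-threshold counterfactual
    for softmax decision noise.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
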