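Package: dapapkpd
Title: Population Pharmacokinetic-Pharmacodynamic Modelling of Dapagliflozin
    and HbA1c Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic-pharmacodynamic (PK-PD)
    analysis of once-daily oral dapagliflozin in patients with type 2
    diabetes mellitus. Implements a one-compartment first-order absorption
    pharmacokinetic model with a body-weight power covariate on apparent
    clearance, an HbA1c turnover (indirect-response) model with an Emax
    drug effect, a first-order conditional (FOCE/Laplace) marginal-likelihood
    estimator for nonlinear mixed-effects models with log-normal
    inter-individual variability, stepwise covariate selection, model
    qualification by prediction-corrected visual predictive checks and
    nonparametric bootstrap, dose-scenario simulation of one-year HbA1c
    trajectories, and a synthetic virtual-cohort generator that emulates
    the trough-sampled real-world study design the models were built for.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    statmod,
    tidyr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
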