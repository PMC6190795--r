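Package: cefapop
Title: Population Pharmacokinetics and PK/PD Cutoff Simulation for
    Intravenous Cefazolin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of two-compartment intravenous
    bolus pharmacokinetics, built around prophylactic cefazolin dosing in
    dogs. Provides a FOCE-type (Laplace conditional, extended least squares)
    estimation engine with exponential between-subject variability on a full
    omega covariance, a combined additive plus proportional residual model,
    stepwise covariate model building under BIC add/delete thresholds,
    nonparametric bootstrap and visual predictive check diagnostics, and a
    Monte Carlo probability-of-target-attainment engine that derives an
    fT>MIC-based PK/PD susceptibility cutoff. A synthetic study generator
    reproduces the sampling design and covariate structure of a perioperative
    canine population so that every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
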