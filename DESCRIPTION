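Package: hcqpk
Title: Population Pharmacokinetics of Hydroxychloroquine and Its Metabolites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear mixed-effects population pharmacokinetic modelling of
    whole-blood hydroxychloroquine (HCQ) and its three desethyl metabolites
    (desethylhydroxychloroquine, desethylchloroquine, didesethylchloroquine)
    in hospitalized adults. Provides an analytic solver for the parent plus
    three-metabolite compartment cascade under arbitrary multi-dose regimens,
    log-normal between-subject variability with combined proportional and
    additive residual error, approximate marginal-likelihood (Laplace/FOCE-type)
    estimation with empirical Bayes estimates, shrinkage, stepwise covariate
    selection and subject-resampling bootstrap, Monte-Carlo dosing-regimen
    simulation of trough concentrations, visual predictive checks and
    normalized prediction distribution errors, a synthetic-cohort generator
    with known ground truth, and exposure-outcome (trough versus length of
    hospital stay and clinical outcome) analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
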