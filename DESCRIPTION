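Package: vanpop
Title: Population Pharmacokinetics and Dosing Simulation of Vancomycin in
    Pediatric Liver Transplant Recipients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects (population) pharmacokinetic modelling of
    intravenous vancomycin in pediatric liver-transplant recipients. Implements
    a one-compartment intermittent-infusion structural model with allometric
    weight scaling and power-law covariate effects (serum creatinine, days from
    transplantation), Laplace/FOCE marginal-likelihood estimation with stepwise
    covariate selection, empirical Bayes (post hoc) individual estimates and
    shrinkage, nonparametric bootstrap and visual predictive check validation,
    and Monte Carlo probability-of-target-attainment simulations for trough and
    AUC24/MIC dosing targets. Includes a synthetic study-population generator
    emulating the covariate distributions and trough-based therapeutic drug
    monitoring design of a pediatric liver-transplant cohort, and NONMEM-style
    dataset input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    deSolve,
    jsonlite
Config/testthat/edition: 3
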