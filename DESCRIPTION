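Package: cfmediate
Title: Bayesian Counterfactual Mediation Analysis for Two-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal mediation analysis for randomised two-arm trials with
    continuous mediators and binary outcomes. Fits Bayesian linear models for
    standardised mediators and Bayesian logistic models for outcomes via exact
    Polya-Gamma Gibbs sampling, and combines them through Pearl's mediation
    formulas into natural direct and natural indirect effect odds ratios,
    marginalised over the observed covariate distribution by Gauss-Hermite
    quadrature or Monte Carlo integration. Includes a seeded synthetic trial
    generator with stratified permuted-block randomisation and missing-at-random
    attrition, a brute-force counterfactual oracle for ground-truth effects,
    hierarchical (Cauchy-prior) attrition models, and multiple imputation by
    chained equations as a missing-data sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    coda,
    stats,
    utils,
    pracma
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags,
    jsonlite
Config/testthat/edition: 3
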