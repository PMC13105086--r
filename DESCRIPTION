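Package: htelearn
Title: Heterogeneous Treatment Effect Estimation and Testing with Bagged Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiparametric estimation and testing of heterogeneous treatment
    effects (HTE) from observational data with a continuous outcome, a binary
    treatment, and tabular covariates. Implements the R-learner based on the
    Robinson transformation with K-fold cross-fitted nuisance estimation, and a
    revised (centered) variant that removes the constant treatment effect before
    re-estimating the outcome regression, stabilising inference when the average
    effect is large. Nuisance functions are fit with bagged multilayer
    perceptrons (compiled Adam-trained networks with out-of-bag filtering of
    poorly performing ensemble members); a fast ridge learner is provided as an
    alternative. The global null of no effect heterogeneity is tested with an
    analytic kernel score test whose chi-square-mixture null distribution is
    evaluated by characteristic-function inversion, and with a cross-fitted
    within-arm permutation test. Includes a simulator for registry-like
    confounded data, simulation-grid drivers for Type I error, power and
    estimation-accuracy experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
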