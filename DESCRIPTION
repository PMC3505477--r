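Package: plps
Title: Partitioned LASSO-Patternsearch for Binary Risk-Pattern Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies main effects and second/third-order interaction
    patterns of dichotomous predictors via l1-penalized logistic regression.
    Implements the two-stage partitioned LASSO-Patternsearch algorithm:
    a parallelizable screening stage that solves reduced pattern-search
    subproblems over partitions of the predictors, and an aggregation stage
    with separate penalties for main effects and interactions tuned by the
    balanced BGACV2/BGACV3 criteria, followed by an unpenalized logistic
    refit with backward elimination under BGACV. Includes synthetic-data
    generators for correlated thresholded-Gaussian binary designs,
    replicated simulation drivers, and evaluation utilities (pattern and
    variable selection counts, prevalence filtering, AUC, stratified
    cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
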