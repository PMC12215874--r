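Package: snakeswarm
Title: Particle Snake Swarm Optimization for Wrapper Feature Selection in Clinical Tabular Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bound-constrained minimization by the Snake Optimizer (SO), Particle
    Swarm Optimization (PSO), and their hybrid (PSSO), with seeded deterministic
    runs and convergence tracing.  The optimizers drive a wrapper engine that
    jointly selects feature subsets and tunes classifier hyperparameters for
    tabular disease classification, balancing cross-validated error against
    subset size.  Includes the surrounding study machinery: preprocessing
    (imputation, standardization, one-hot encoding, stratified splitting),
    SMOTE-ENN class rebalancing, a multiclass metric suite with one-vs-rest
    ROC/AUC and ANOVA comparison, a perturbation-based robustness protocol,
    and seeded generators for thyroid-like synthetic data and analytic
    benchmark objectives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    rpart,
    e1071,
    Rcpp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
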