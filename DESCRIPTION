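Package: rarebn
Title: Bayesian Network Dissection of Rare-Variant Disease Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint modelling of environmental exposures, annotation-weighted
    rare-variant gene burden scores, quantitative traits and a binary disease
    outcome with constrained linear-Gaussian Bayesian networks.  Provides a
    replicate-aware simulator of exome-style cohorts with known causal
    architecture, weighted-sum burden scoring stratified by functional
    annotation with a data-estimated nonsynonymous weight, per-replicate
    marginal screening with cross-replicate retention (and a bootstrap
    variant), Metropolis-Hastings structure sampling over typed-node DAGs
    with linear Gaussian node densities, replicate-consensus edge confidence
    scoring, and network-guided disease risk prediction with support vector
    machines and a LASSO comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
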