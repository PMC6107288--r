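Package: ggminfer
Title: Statistical Inference for Large-Scale Gaussian Graphical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigorous statistical inference of conditional dependence in
    high-dimensional Gaussian graphical models for gene co-expression
    network analysis. Implements four asymptotically normal estimators of
    precision-matrix entries -- the bivariate nodewise scaled Lasso, the
    de-sparsified nodewise scaled Lasso, the de-sparsified graphical Lasso,
    and bias-corrected residual-covariance test statistics with scaled
    Lasso or tuned Lasso regressions -- together with individual inference
    (estimates, confidence intervals, p-values) and global simultaneous
    inference with false-discovery-rate control over all gene pairs.
    Includes synthetic graph generators (band, hub, Erdos-Renyi,
    scale-free), count-data transforms for single-cell workflows,
    evaluation metrics, and export of Cytoscape-compatible edge tables.
    The convex-optimisation core (cyclical coordinate descent with
    covariance updates, warm starts, and sparsity-aware matrix products)
    is implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
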