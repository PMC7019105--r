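Package: scnormbench
Title: Single-Cell RNA-Seq Normalization Methods and Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements seven normalization methods for single-cell RNA-seq
    count matrices (simple library-size scaling, SAMstrt-style spike-in
    resampling, a hierarchical Poisson-Gamma Bayesian model, per-cell gamma
    regression against spike-in concentrations, pooled size-factor
    deconvolution, quantile-regression count-depth correction, and a stable
    gene linear-model transform), together with a negative-binomial count
    simulator with ground-truth tracking and an evaluation harness based on
    repeated KNN classification scored by Cohen's kappa, BH-adjusted
    differential-expression screening, and PCA embedding. A command-line
    interface ties the pieces into a simulate/normalize/evaluate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    scran
Config/testthat/edition: 3
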