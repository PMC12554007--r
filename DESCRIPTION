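Package: sparsevcm
Title: Sparse Smooth Varying-Coefficient Models for Regional mQTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits high-dimensional binomial varying-coefficient models for
    regional methylation quantitative trait locus (mQTL) mapping from
    bisulfite sequencing read counts. Position-varying SNP effects are
    represented with natural cubic splines and estimated under a composite
    sparsity-smoothness penalty that selects whole coefficient functions
    while controlling their curvature. Estimation uses proximal gradient
    descent with backtracking line search, regularization paths anchored at
    an analytic penalty bound, K-fold cross-validation with the
    one-standard-error rule, and an adaptive covariate-specific penalty.
    Includes a simulation generator for regional methylation data with
    block-correlated genotypes, evaluation metrics for estimation,
    prediction and selection accuracy, LD pruning, and readers for
    long-format methylation count tables and genotype matrices (TSV or VCF).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
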