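Package: irnet
Title: Integrative Regression Networks from Structured Sparse Multi-Output Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds integrative association networks between two genomic
    profiles (e.g. gene-level DNA methylation features and mRNA expression
    traits) measured on the same samples. Four penalized multi-output
    regressions of traits on features are fitted (lasso, graph-guided fused
    lasso, sparse group lasso, and a jointly input/output-structured lasso);
    each coefficient matrix is converted into feature-side and trait-side
    similarity networks via a K-nearest-neighbour scaled exponential kernel;
    the per-method networks are merged by iterative similarity network
    fusion; and significant edges are selected with a permutation-derived
    weight cutoff. Includes network diagnostics (density, clustering,
    scale-freeness R-squared), a Bonferroni-corrected correlation-network
    baseline, top-k coefficient overlap summaries, and a synthetic-data
    generator with planted group- and block-structured sparse coefficients
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
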