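Package: spatfuse
Title: Sparse Spatially Varying Coefficient Regression for Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimation of location-specific, sparse, spatially coherent
    regression coefficient fields linking a spatial response feature (for
    example a gene's expression across spots or cells) to high-dimensional
    spatial predictors (other genes, deconvolved cell-type proportions,
    neighborhood composition, niche indicators). The coefficient field is
    fit by first-order optimization of a convex objective combining a graph
    fused-lasso penalty on a k-nearest-neighbor graph or Euclidean minimum
    spanning tree, an element-wise lasso penalty, and a group-lasso penalty
    over each predictor's whole field. Includes spatially blocked
    cross-validation for penalty selection, post-hoc cluster-wise refitting
    with FDR control, cell-type-attributed expression with non-negativity
    and presence constraints, Moran's I permutation tests for spatially
    variable genes, cross-cell-type gene covariation tensors, local
    neighborhood and niche context features, and a synthetic-data benchmark
    scored by Adjusted Rand Index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ape,
    igraph,
    optparse
Config/testthat/edition: 3
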