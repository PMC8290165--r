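Package: vasculograph
Title: Graph-Based Topological Analysis of Micro-CT Vascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Quantifies the topological connectivity of contrast-filled
    vascular networks imaged by micro-computed tomography. Implements vessel
    segmentation (gray-map transformation, multiscale Hessian tubularity
    enhancement, threshold segmentation, seeded region growing),
    topology-preserving 3D skeletonization, skeleton-to-graph conversion by
    the 26-neighbor rule with connected-component merging of junction
    clusters, and the network metrics clustering coefficient, average path
    length and normalized network structure entropy, together with
    normality-gated two-group statistics. Includes a synthetic vascular
    phantom generator with normal and tumor-like phenotypes and paired
    ground-truth networks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    Matrix,
    methods,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    nortest,
    pracma,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
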