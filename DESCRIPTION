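Package: clonespace
Title: Clonal Embeddings from Lineage-Coupled Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional embeddings of clones from lineage-coupled
    single-cell expression data. Cells sharing a lineage barcode or TCR
    clonotype are summarised through a clone-by-clone neighbour co-occurrence
    matrix built from a k-nearest-neighbour graph in a latent expression
    space, which is then factorised either with a skip-gram multinomial
    model or with Poisson GLM-PCA. Downstream tools cover clone-graph
    community detection, archetypal analysis, clone-level differential
    expression, graph-aware supervised PCA, Moran's I permutation testing,
    cross-cohort alignment of clonal embeddings via mutual-nearest-neighbour
    anchors, and a synthetic benchmark suite with distribution-distance
    baselines (MMD, Sinkhorn divergence, energy distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
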