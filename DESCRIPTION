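Package: awmv
Title: Adaptively Weighted Multi-View Matrix Factorization for Single-Cell Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint non-negative matrix factorization of parallel scRNA-seq and
    scATAC-seq data profiled on the same cells. Four non-negative views (linked
    gene expression, linked gene activity, unlinked genes, unlinked peaks) are
    factorized simultaneously with per-view adaptive weights learned by an
    entropy-regularized softmax of reconstruction errors, a shared consensus
    cell-factor matrix, and a coupling penalty tying the basis matrices of the
    two linked views. Includes preprocessing (distance-weighted gene activity
    scoring from ATAC peaks, variance-stabilized selection of highly variable
    genes, view construction and normalization), Louvain clustering of the
    consensus factors, clustering evaluation (NMI, ARI, RAGI via per-gene Gini
    indices), and a synthetic multi-view data generator with planted cluster
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
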