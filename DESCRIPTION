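Package: scvuln
Title: Identifying Single-Cell Clusters Vulnerable to Genetic Risk Gene Sets
Version: 0.1.0
Authors@R:
    person("scvuln", "maintainers", email = "maintainers@scvuln.org", role = c("aut", "cre"))
Description: A reusable single-cell RNA-seq analysis pipeline for locating cell
    clusters with enriched expression of genetic risk-factor gene sets
    (e.g. monogenic autism risk genes or the 16p11.2 microdeletion locus).
    Provides quality-control filters and library-size normalization,
    variance-to-mean-ratio highly-variable-gene selection, PCA with jackstraw
    significance testing, Louvain community detection on Jaccard-weighted
    k-nearest-neighbour graphs, one-vs-rest Wilcoxon differential expression
    with risk-set summaries, gene-set-restricted neighbour-voting AUROC
    cluster similarity, hypergeometric over-representation analysis, and
    cross-dataset diagonal CCA with k-nearest-neighbour majority-vote label
    transfer. Ships a negative-binomial synthetic-data generator with
    machine-readable ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
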