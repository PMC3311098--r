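Package: mnalign
Title: Scalable Global Alignment of Multiple Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global alignment of two or more protein-protein interaction
    networks into disjoint match-sets of putative functional orthologs.
    Implements topology-aware preprocessing of a sparse cross-network
    sequence-similarity matrix, agglomerative clustering of proteins under
    the I1/I2 criterion functions, clustering-based seed generation,
    priority-queue seed expansion with a parametric match-set merging
    criterion, and alignment of remaining proteins. Ships an evaluation
    metric suite (weighted average similarity, conserved and strictly
    conserved edges, coverage, conserved-edge rate, hypergeometric GO-term
    enrichment), a maximum-weight bipartite matching baseline for pairwise
    alignment, and a planted-ortholog synthetic network generator for
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
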