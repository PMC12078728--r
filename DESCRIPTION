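Package: toxicoclust
Title: Robust Hierarchical Co-Clustering of Toxicogenomic Fold-Change Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-way hierarchical co-clustering of fold-change gene-expression
    matrices (genes by doses-of-chemicals) with a robust mode that applies a
    bounded logistic transform before clustering, so that outlying fold
    changes cannot dominate the distances. Co-cluster blocks are ranked onto
    the principal diagonal by their mean transformed fold change and called
    significantly up- or down-regulatory with a Shewhart-style control chart.
    Includes a block-model simulator with casewise (Tukey-Huber) and cellwise
    contamination, clustering error-rate and sensitivity-curve robustness
    diagnostics, and bipartite gene-chemical network export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
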