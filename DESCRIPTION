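Package: protspace
Title: Protein Sequence Embedding and Cluster-Structure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Embeds amino acid sequences as numeric vectors by training
    skip-gram 3-mer models (Protvec-style summation embedding) or by
    reduced-alphabet k-mer frequency profiles, estimates the number of
    clusters in an embedding with a bootstrapped Calinski-Harabasz index
    over agglomerative dendrogram cuts, compares embedding dendrograms
    against multi-level functional annotation hierarchies via tanglegram
    entanglement, clusters unannotated sequences with k-means, and
    verifies clusters by pairwise global-alignment identity. Includes a
    synthetic protein-family generator with a planted mock ontology so
    the full pipeline is testable without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    ape,
    methods,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
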