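Package: walkcensus
Title: Walk-Based Subgraph Census Embedding and Classification of
    Structural Brain Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Embeds undirected networks in a feature space defined by a
    census of subgraphs traceable by fixed-length walks (149 isomorphism
    classes at walk length eight), reduces the embedding with principal
    components analysis, classifies two-group cohorts with a nested
    cross-validated linear soft-margin support vector machine, assesses
    significance by label permutation, and extracts discriminative
    subgraph features by recursive feature elimination.  Also provides
    classical graph statistics (clustering, geodesic length,
    transitivity, degree survival), a giant-component rule for choosing
    network resolution, threshold-sweep robustness analysis, and a
    synthetic two-class cohort generator with planted motif differences
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
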