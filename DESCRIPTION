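Package: multibrain
Title: Multimodal Multilayer Brain Network Centrality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of multimodal multiplex brain networks.
    Builds per-modality connectivity matrices (phase lag index on band-filtered
    MEG-like time series, absolutized Pearson correlation for BOLD-like series,
    validated streamline-count matrices), extracts binary minimum spanning tree
    backbones with Kruskal's algorithm on inverted weights, assembles the
    supra-adjacency matrix of the resulting multiplex network, and computes
    single-layer and multilayer eigenvector centrality with subnetwork
    aggregation (e.g., the fronto-parietal network). Includes an edge
    significance procedure against degree-, weight-, and strength-preserving
    null ensembles, a statistical layer with blockwise stepwise regression,
    collinearity diagnostics, hierarchical quadratic age models and
    leave-one-out cross-validated R-squared, and a synthetic multimodal cohort
    generator with planted integration effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
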