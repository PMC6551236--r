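Package: unicent
Title: Unified Iterative Centrality for Signed Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus centrality analysis for signed, weighted, undirected
    biological networks such as microbial co-occurrence and gene co-expression
    networks. Implements signed path-based centrality backbones (degree,
    closeness and betweenness built on maximum edge-weight-product paths), an
    iterative de-biasing loop that repeatedly extracts the most central node
    together with its stable-triad dependency edges, and a consensus stage
    that reconciles the backbones' discovery traces into a single ranked set
    of central nodes and supernodes. Includes seeded generators for modular
    and scale-free signed test networks, rank-vector expansion and Spearman
    comparison utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
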