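Package: sourcetrace
Title: Centrality-Based Localization of Propagation Sources in Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for locating the origin
    ("patient zero") of a spreading process on an undirected network.
    Generates discrete-time SIR and Independent Cascade outbreaks on real or
    synthetic graphs (Watts-Strogatz small-world, preferential-attachment
    scale-free), extracts the infection subgraph, ranks its nodes with a
    catalog of 25 centrality measures plus Jordan-center and Netsleuth
    baselines, optionally expands candidate sets by one or two hops, and
    scores detection with confusion-matrix metrics (PPV, TPR, F1) and the
    distance-based GADE and ADE statistics. Includes a reproducible
    experiment-grid runner that aggregates results into ranked method tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
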