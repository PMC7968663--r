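Package: dtnet
Title: Topology, Centrality, Communities and Minimal Drug Sets for
    Drug-Target Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds directed drug-target interaction networks from
    DrugBank-style XML exports or plain edge tables and characterises
    their landscape: dual-role (drug-and-target) detection and
    bipartiteness, weakly connected components, degree distributions with
    power-law exponent fitting (log-log least squares and discrete
    maximum likelihood), clustering profiles, degree, closeness,
    betweenness and eigenvector centralities computed from first
    principles, seeded multilevel (Louvain) community detection with
    Newman-Girvan modularity, drug coregulation projections on shared
    targets, a randomized minimal covering-drug-set reduction, and a
    hypergeometric over-representation test against user-supplied
    annotations. A synthetic-network generator with scale-free margins,
    dual-role nodes and isolated drug-target pairs makes every stage of
    the pipeline testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
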