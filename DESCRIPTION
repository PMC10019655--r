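Package: HerbNetPharm
Title: Network Pharmacology Inference for Herb Pairs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for network-pharmacology analysis of herbal combinations:
    co-prescription herb networks built from binary herb-by-prescription
    incidence matrices (one-mode projection, Jaccard and Pearson similarity),
    ADME screening of candidate compounds by oral bioavailability and
    drug-likeness, target-set algebra against disease gene lists, scored
    protein-protein interaction networks with degree and betweenness
    centrality key-target screening, spectral k-means clustering of key-target
    subnetworks, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, and assembly of bipartite compound-target
    networks. Includes seeded synthetic-data generators that plant recoverable
    structure in every input so the full pipeline is testable offline, and a
    single-configuration pipeline driver with Cytoscape-compatible exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
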