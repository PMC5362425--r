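Package: netpharm
Title: Network Pharmacology Target Identification for Herbal Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for in-silico target identification of
    multi-herb formulas: screens compounds by oral bioavailability and
    drug-likeness, builds the compound-target bipartite network, merges
    disease-target lists from multiple sources, intersects seed-expanded
    protein-protein interaction networks, applies a two-stage
    median-threshold topological filter over six centrality measures
    (degree, betweenness, closeness, eigenvector, edge-clustering-based
    network centrality, and local average connectivity) to nominate
    candidate therapeutic targets, and runs hypergeometric gene-set
    enrichment with Benjamini-Hochberg correction and kappa-statistic
    term grouping. Includes a seeded synthetic-data generator with a
    planted ground-truth module so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
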