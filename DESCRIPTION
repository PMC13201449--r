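Package: netpharm
Title: Network Pharmacology Screening, Annotation and Core-Target Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of the computational workflow used in
    network-pharmacology studies of multi-component natural products: compound
    drug-likeness screening (Lipinski, Ghose, Veber, Egan and Muegge rule sets
    plus the BOILED-Egg gastrointestinal-absorption ellipse), high-resolution
    mass-spectrometry peak annotation by monoisotopic adduct mass within a ppm
    tolerance, multi-database disease-target integration, compound-target and
    compound-disease-target network construction with per-node centrality
    profiles, protein-protein interaction core-target screening by an iterative
    above-median quorum over six centrality metrics (degree, betweenness,
    closeness, eigenvector, local average connectivity, and the edge-clustering
    network-centrality sum), hypergeometric over-representation analysis of
    gene lists against GMT collections, and docking-score triage. Seeded
    synthetic-data generators with known ground truth emulate every
    web-service-derived input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
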