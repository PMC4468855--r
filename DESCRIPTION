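Package: moonnet
Title: Extreme Multifunctional Protein Detection from Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects extreme multifunctional (EMF) protein candidates from an
    undirected protein-protein interaction network by combining overlapping
    graph clustering (a re-implementation of the OCG centered-clique /
    modularity-gain algorithm), majority-rule Gene Ontology annotation of
    clusters, and hypergeometric GO term-pair association probabilities
    (annotation and interaction co-occurrence) with Bonferroni-style e-value
    correction. Candidates are proteins found at the intersection of clusters
    annotated to mutually dissimilar biological processes. Includes
    randomization controls (annotation shuffling, uniform and
    degree-preserving edge rewiring, probability reshuffling), leave-one-out
    annotation recovery, known-gene-set enrichment, topological
    characterization of candidate groups, and a seeded generator of synthetic
    networks with planted overlapping modules and planted EMF nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
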