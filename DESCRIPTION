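Package: netprofiler
Title: Reaction-Network Exploration and Cell-Lineage Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools that couple bioregulatory reaction-network analysis with
    cytohistological RNA-seq expression profiling. Reads and writes
    Reactome-dialect SBML into a bipartite species-reaction network with
    species role classification (system input, output, mediator), depth-based
    subgraph pruning, GraphViz DOT and SIF export, offline HGNC identifier
    mapping and SBO term labelling, pathway index search with parent/child
    relation lookup, cross-model species overlap and knowledge-gap detection,
    and prototype kinetic-law injection (mass action, Michaelis-Menten) with a
    deterministic RK4 sanity simulator. The expression side builds a
    lineage-by-gene median nTPM matrix from Human Protein Atlas style
    single-cell tables, computes per-cluster dispersion statistics, Min-Max
    normalizes features, and classifies query expression vectors to their
    nearest cell lineage by Manhattan distance, with per-gene z-score
    differential expression profiles. Deterministic synthetic-data generators
    with ground-truth manifests make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    xml2,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
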