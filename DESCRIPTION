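Package: diffcent
Title: Differential Network Centrality for Cancer Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate cancer driver genes by comparing
    graph-theoretical centrality profiles of per-patient normal and tumor
    protein-protein interaction subnetworks. For each patient instance a
    normal graph (interactome induced on expressed genes) and a tumor graph
    (induced on expressed, non-mutated genes) are built; per-gene weights
    aggregate absolute centrality differences (betweenness, clustering
    coefficient, first- and second-order degree) or structural similarities
    (random-walk and shortest-path proximity column correlations,
    neighborhood Jaccard indices) across all instances. Ranked gene lists
    can be filtered with the GWMIN2 greedy maximum-weight-independent-set
    heuristic to suppress guilt-by-association, and evaluated with top-k
    percent ROC / precision-recall sweeps, a Gene Ontology consistency
    score with level-restricted annotations, and a network-rewiring
    robustness experiment. A seeded synthetic-data generator produces
    scale-free interactomes, paired expression and mutation instances with
    planted driver genes, and toy ontologies, so the whole pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
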