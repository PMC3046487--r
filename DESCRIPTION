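Package: genesisnet
Title: Gene Age and Origin Classification with Interaction Network
    Assortativity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies genes into age (pre whole-genome-duplication, WGD,
    post-WGD) and origin (duplicate, novel) groups from evolutionary
    evidence tables (homologous family maps, ancestral gene-order
    reconstructions, ortholog phylogenetic profiles), quantifies the
    integration of each group into a protein-protein interaction network
    (degree, betweenness centrality, length-normalized variants), and
    tests group-level interaction preferences against a degree-preserving
    randomized-network null with empirical p-values and Glass's Delta
    effect sizes.  Includes Mann-Whitney group comparisons, hypergeometric
    term enrichment, a ground-truthed synthetic-data generator based on a
    degree-corrected block model, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
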