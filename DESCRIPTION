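Package: hubnet
Title: Hub Roles, Community Structure and Link Centrality in Protein
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the roles of highly connected proteins
    (hubs) in protein-protein interaction networks. Implements
    co-expression based hub classification into "date" and "party" hubs
    via the average Pearson correlation with interaction partners
    (avPCC), Hartigan's dip test of unimodality with a bootstrap null,
    kernel-density mode counting at varying bandwidths, node and link
    betweenness centrality with targeted hub-deletion experiments,
    resolution-tunable Potts/modularity community detection with
    Guimera-Amaral topological role cartography, per-node Jaccard
    comparison of community partitions across data sets, and set
    information content (SIC) based functional similarity of
    interacting proteins. A synthetic-data module generates planted
    modular networks, correlated expression profiles and toy ontologies
    so that every stage of the analysis can be exercised and tested
    without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
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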