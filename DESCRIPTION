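Package: grnevo
Title: Evolutionary Structure of Gene Regulatory Network Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes how gene evolutionary rates and ages are organized on
    weighted, partially directed gene regulatory networks. Annotates genes
    with per-site evolutionary rates (from amino-acid alignments and a dated
    phylogeny) and phylostratigraphic ages (from ortholog presence across
    ordered clades), detects communities by directed weighted modularity,
    tests gene groups for evolutionary homogeneity against degree-preserving
    rewiring and equal-size random-set nulls, computes degree, PageRank and
    betweenness centrality, and quantifies topological placement of gene sets
    with set-efficiency and interset-efficiency measures, including
    cumulative set-efficiency curves with shuffled-order controls. Includes a
    synthetic-data generator with planted core-periphery community structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Rcpp,
    ape,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
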