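Package: lygfam
Title: Gene Family Evolution Analysis for Goose-Type Lysozyme
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for studying the evolution of the vertebrate
    goose-type lysozyme (lysozyme g) gene family, and of tandemly duplicating
    gene families like it. Provides progressive protein alignment with
    perturbation-based column confidence trimming, neighbor-joining phylogeny
    with bootstrap support and outgroup rooting, gene-tree/species-tree
    reconciliation with duplication age labelling, loss counting and paralog
    naming, catalytic-residue and secretion-status scanning against mature
    reference numbering with a copy-number compensation cross-tab, and
    synteny neighborhood and tandem-cluster analysis. A birth-death gene
    family simulator supplies ground-truthed synthetic families so that every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    phytools,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
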