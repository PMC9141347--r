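Package: tecurate
Title: Curation of Transposable Element Consensus Libraries and Mobilome
    Analysis
Version: 0.1.0
Authors@R:
    person("Repeat", "Curator", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning de-novo consensus models of interspersed
    repeats into a curated transposable-element (TE) library. Implements
    the standard curation cascade (redundancy clustering at 90/90,
    copy-number and full-length screening, exon-overlap and tandem-repeat
    filters, tRNA screening), protein/profile evidence integration with
    low-complexity vetting and family classification (LTR Gypsy-like,
    LINE-like, SINE candidates), per-genome mobilome summaries (merged
    repeat coverage, presence/absence matrices, GC-median splits), and
    Sankoff gain/loss parsimony with exhaustive enumeration of optimal
    invasion/extinction scenarios on a rooted species tree. Ships a
    synthetic-genome simulator that plants TEs and decoys with full
    ground truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    igraph,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
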