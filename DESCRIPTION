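Package: trantyper
Title: Typing and Host-Range Prediction for Conjugative Plasmid TraN Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Survey and typing pipeline for TraN, the outer-membrane
    mating-pair-stabilization protein of F-type (MPF_F) conjugation systems
    carried by IncF, IncA/C, IncH and Acinetobacter baumannii plasmids.
    Extracts TraN candidates from GenBank plasmid records by annotation,
    computes exact global pairwise protein alignments and percent-similarity
    matrices, assigns each protein to the TraN_S/TraN_M/TraN_L/TraN_V size
    and family typology with subclade and receptor-binding tip-domain
    mapping against reference profiles, builds midpoint-rooted
    neighbor-joining trees, summarizes corpus-level copy-number, size-class
    and resistance-gene associations, predicts receptor dependency and
    recipient host range from a curated evidence table, and simulates fully
    ground-truthed synthetic plasmid corpora for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
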