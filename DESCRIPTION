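Package: segext
Title: Assembly of Unique and Copied Genomic Insertions by Segment Extension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles the sequence content of genomic insertions -- unique,
    copied from elsewhere in the reference, or a mixture of the two -- from
    paired-end short reads. Read pairs are classified by their mapping
    signature (one-end-anchored, orphan, discordant, concordant,
    over-coverage) into an insertion read set; reference-flank segments are
    then extended one consensus column at a time using reads anchored by
    their mapped mate, with an FM-index over the concatenated insertion
    reads replacing the naive per-read anchor scan. Includes a paired-end
    read simulator with planted-insertion truth sets and an edit-distance
    based accuracy evaluator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    withr,
    generics,
    ggplot2,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
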