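Package: oligobarcodes
Title: Penalty-Based Selection of Optimal Oligonucleotide Barcode Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design of oligonucleotide molecular-barcode (UMI) sets for
    sequencing applications. Candidate barcodes are scored on five sequence
    factors (GC content, homopolymer length, dinucleotide simple-sequence
    repeats, pairwise Hamming distance and inter-barcode complementarity)
    with penalty curves calibrated on random-barcode distributions, and a
    set of N barcodes is refined by iterative probabilistic exclusion and
    replacement until the weighted total penalty stops improving. Includes
    tools to characterize random barcode sets, refit the penalty curves,
    sweep weights and replacement rates, and compare barcode sets on six
    criteria, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
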