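Package: panrep
Title: Phage-Display Biopanning Repertoire Analysis for VHH Nanobody Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing in vivo phage-display biopanning of VHH
    (nanobody) libraries sequenced by paired-end amplicon sequencing.
    Reconstructs full-length VHH coding sequences from read pairs, annotates
    framework and CDR regions against a scaffold consensus, builds clonotype
    tables, computes clonality and Hill-number diversity statistics with
    rarefaction and Chao1-style extrapolation, tracks clones across selection
    rounds, applies a late-over-early enrichment filter, and scores cell-subtype
    selectivity. Includes a stochastic biopanning simulator that emits paired
    FASTQ reads with ground-truth tables so the whole pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
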