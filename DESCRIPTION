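Package: duplexlb
Title: Duplex Sequencing Consensus Calling and Analytical Validation for
    Liquid Biopsy Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for highly sensitive detection of low variant allele
    frequency (VAF) variants from duplex-tagged sequencing reads, as used in
    liquid biopsy (circulating free DNA) assays run alongside a tissue
    workflow. Groups reads into strand families by duplex tag and fragment
    coordinates, builds single-strand (SSCS) and duplex (DCS) consensus
    reads by per-base majority vote, and calls variants from pileups in two
    modes: a liquid-biopsy mode on duplex consensus reads with a limit of
    blank (LOB) of 0.25% VAF and an eight-consensus-read support rule, and a
    tissue mode on raw reads with a 5% LOB. Implements the full analytical
    validation of such an assay (limit of blank, limit of detection, limit
    of quantification, sensitivity, positive predictive value, trueness,
    repeatability and total error) and bundles a duplex read simulator with
    spike-in reference series and in silico dilution so that the whole
    workflow can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
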