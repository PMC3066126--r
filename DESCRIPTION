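Package: germmir
Title: Plant miRNA Discovery from Small RNA Sequencing of Imbibed Seed
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for plant microRNA discovery from deep
    small-RNA sequencing: adapter and quality cleaning of raw reads,
    collapsing to unique tags, perfect-match placement on a reference
    genome, partitioning of tags into noncoding-RNA and gene-model
    classes, identification of conserved miRNAs against a miRBase-style
    reference, prediction of novel miRNAs from folded genomic hairpins
    screened by the minimal folding free energy index (MFEI), miRNA*
    duplex support, cross-library confirmation, and plant-style miRNA
    target prediction with positional duplex rules. Includes a fully
    deterministic synthetic-data generator with a ground-truth manifest
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
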