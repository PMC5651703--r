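Package: starrvar
Title: Regulatory Variant Screening from STARR-Seq Reporter Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls SNP-containing genomic fragments with positive or negative
    transcription-regulatory activity from paired input/output reporter
    libraries (STARR-seq/MPRA style screens) and detects regulatory variants
    whose two alleles confer different activity. Implements median-of-ratios
    normalization with a negative-binomial Wald test for element activity,
    allelic-imbalance testing via the two-sided Fisher exact test with a
    conditional maximum-likelihood odds ratio, annotation-peak overlap
    enrichment, position-weight-matrix allele delta scoring, a pooled-capture
    allele-coverage simulation, and a two-step residualizing eQTL regression.
    Ships a synthetic-screen generator with known ground truth so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr,
    rtracklayer
Config/testthat/edition: 3
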