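Package: linemarker
Title: Line-Unique Fixed SNP Discovery from Pooled Resequencing of Selected Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies fixed, line-unique, amino-acid-changing single nucleotide
    variants from pooled whole-genome resequencing of two divergently selected
    lines. Provides strand-aware coding-effect annotation with HGVS-like c. and
    p. notation, a depth/allele-fraction/region/impact filter cascade with
    per-stage tallies, allele-specific PCR primer design with a deliberate
    destabilizing mismatch, and a synthetic pool-seq data generator with a
    planted-truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    S4Vectors,
    methods,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
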