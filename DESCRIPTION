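Package: accvar
Title: Cell-Type-Resolved Chromatin Accessibility Scoring and
    Prioritization of Noncoding Disease Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nominates causal noncoding SNPs for complex eye disease from
    single-cell multiome data. Builds per-cell-type base-resolution Tn5
    insertion tracks from fragment files, applies quality-control and
    peak-reproducibility filters, links peaks to genes through
    co-accessibility and accessibility-expression correlation, annotates
    SNPs with chromatin loops and eQTL evidence, and scores allele effects
    on predicted accessibility with a base-resolution convolutional
    sequence model (profile multinomial likelihood plus log-counts head),
    combining per-cell-type one-sided Poisson tests with Fisher's method
    and Benjamini-Hochberg correction into putative high-effect calls. A
    synthetic multiome generator with planted motifs, LD blocks, loops and
    eQTLs provides ground truth for end-to-end validation at desk scale.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
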