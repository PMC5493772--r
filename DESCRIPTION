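Package: ykofit
Title: Comparative Fitness Profiling of Pooled Yeast Deletion Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for barcode-based competitive fitness assays of
    pooled Saccharomyces cerevisiae deletion collections. Calls strain presence
    from barcode-array intensities with a two-component Gaussian mixture fit by
    EM, masks hybridization artifacts on replicate features, normalizes uptags
    and downtags, selects the best tag per strain, applies location-scale batch
    standardization, computes fitness-defect (FD) scores against control
    medians with t-test/Benjamini-Hochberg significance, defines and subtracts
    shared fitness signatures across condition groups, quantifies Bar-seq
    barcodes by Hamming-distance matching with median-of-ratios normalization,
    compares presence rosters across collections, and performs right-sided
    hypergeometric gene-set enrichment with Holm correction. Includes a
    synthetic-data generator that emulates the pooled-screen designs the
    pipeline assumes, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    withr
Config/testthat/edition: 3
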