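Package: ewnscan
Title: Sliding-Window Enhancer-Activity Scoring of Non-Coding Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains a convolutional sequence model of tissue-specific
    enhancer activity, scores biallelic non-coding SNPs for gain or loss
    of enhancer function with a sliding-window essential-window-number
    (EWN) statistic, validates calls with exact binomial tests of allelic
    read imbalance, quantifies transcription-factor motif disruption with
    FDR-calibrated position-weight-matrix scanning, prioritises
    population-differentiated variants by Hudson's FST, and aggregates
    risk alleles into a polygenic risk score evaluated by control-quantile
    case enrichment. Seeded synthetic-data generators (planted-motif
    enhancer sequences, Balding-Nichols two-population allele-frequency
    panels, allelic read counts, liability-model case/control genotypes)
    allow the full pipeline to be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    vcfR,
    jsonlite,
    pROC
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
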