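Package: circprom
Title: Core Promoter Architecture and Circadian Transcription Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies core promoters of circadian genes from sequence
    features, rhythm statistics, and chromatin signals. Provides exact
    position-count-matrix score distributions with balanced FDR/FNR
    thresholds, cosinor (harmonic regression) rhythm detection, TSS-anchored
    coverage-track quantification including Pol II pausing indices and +1
    nucleosome peak calling, a promoter taxonomy with strong circadian
    promoters (SCPs), an expression-matched bootstrap test, a three-state
    Pol II recruitment/initiation/pause-release kinetic model with periodic
    forcing, and a synthetic-data generator so every stage is testable
    without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    stats,
    utils,
    edgeR,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rtracklayer,
    GenomicRanges
LinkingTo: Rcpp
Config/testthat/edition: 3
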