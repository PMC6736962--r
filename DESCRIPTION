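Package: eeldelim
Title: Integrative Species Delimitation for Electric Eels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for integrative species delimitation in
    Electrophorus (electric eels) and similar taxa. Implements Kimura
    two-parameter barcode distances with within/between-lineage divergence
    summaries, automatic barcode-gap partitioning, the single-threshold general
    mixed Yule-coalescent (GMYC) model with likelihood-ratio test, the
    genealogical sorting index with permutation p-values, diagnostic-nucleotide
    screening, an electric organ discharge (EOD) waveform pipeline (conditioning,
    1% duration, Symmlet-4 discrete wavelet features, pairwise-ANOVA feature
    selection, single-linkage clustering, Mahalanobis D2), a Pillai-trace MANOVA
    for niche separation, and seeded synthetic generators for alignments,
    ultrametric trees, EOD pulses and environmental tables so that every stage
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
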