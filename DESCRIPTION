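Package: ovitx
Title: Differential Expression and GO Overrepresentation for Oviductal
    Sperm-Reservoir Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for expression microarray analysis
    of oviductal sperm-reservoir tissue (the avian utero-vaginal junction and
    the porcine utero-tubal junction) under a three-group design (control,
    mating, seminal-fluid infusion). Implements RMA-style preprocessing
    (norm-exp background correction, between-array quantile normalization,
    median-polish probe-set summarization), empirical-Bayes moderated
    t-statistics with a method-of-moments variance prior, Benjamini-Hochberg
    FDR plus a permutation-based experiment-wide significance threshold,
    probe-to-gene list construction (redundancy and uncharacterized-probe
    filtering, volcano classification, treatment overlaps, top-200
    fold-change selection), a binomial GO overrepresentation test with
    expected counts and fold enrichment, and cross-species comparison via
    GO-slim profiles and shared gene families. A seeded synthetic-data
    generator with planted effects makes every stage testable without raw
    arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
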