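Package: acrminer
Title: Structure-Guided Mining of Anti-CRISPR and Anti-Phage Defense Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a structure-guided discovery
    pipeline for phage anti-CRISPR (Acr) and counter-defense proteins and for
    bacterial single-gene anti-phage defense proteins. Provides sequence
    filtration cascades (length, greedy identity clustering, sequence-divergence
    exclusion, isoelectric-point and domain filters), native TM-score structural
    alignment of alpha-carbon traces (Kabsch superposition, iterative dynamic
    programming search), defense-island co-localization mining with marker
    prevalence statistics, fusion detection, and seeded synthetic-data
    generators so the entire pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
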