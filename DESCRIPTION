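Package: coabund
Title: Co-Abundance Network Analysis for Multiplexed Longitudinal Proteomics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for longitudinal tandem-mass-tag (TMT)
    proteomics: reference-channel ratio quantitation across plexes,
    per-protein differential abundance with joint fold-change and p-value
    gates, weighted co-abundance network analysis (signed adjacency,
    topological overlap, average-linkage clustering, dynamic hybrid tree
    cut, module eigenproteins and kME hub ranking), marker-set enrichment
    with Fisher's exact test and hypergeometric over-representation, and
    cross-dataset module concordance.  Includes a synthetic-data generator
    that emulates a multi-plex longitudinal design with planted co-abundance
    modules, plex batch effects and cross-plex missingness, so every stage
    of the pipeline can be validated against known ground truth.
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
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
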