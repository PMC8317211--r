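Package: tmtde
Title: Multi-Batch TMT Proteomics Normalization and Moderated Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for isobaric-label (TMT) proteomics
    quantified across multiple plexes with pooled reference channels. Implements
    sample-loading scaling, trimmed-mean-of-M-values (TMM) factors, internal
    reference scaling (IRS) or linear-model batch correction, quality-control
    summaries (per-group CV, Pearson correlation, PCA), SAM-style s0-moderated
    two-group tests with permutation-based FDR and an ANOVA prefilter,
    cross-comparison overlap accounting with direction concordance,
    hypergeometric gene-set over-representation, and MCODE dense-cluster
    detection on score-filtered protein-protein interaction networks. Ships a
    seeded synthetic-data generator emulating a two-plex, four-group study
    design with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
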