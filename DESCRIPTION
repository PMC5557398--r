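Package: leukfuse
Title: Fusion Transcript Filtering, Junction Screening, and
    Methylation-Expression Integration for Pediatric ALL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a fusion-transcript analysis
    pipeline for pediatric acute lymphoblastic leukemia (ALL)
    transcriptomes: parsing and cascade-filtering of de novo fusion
    candidates, targeted screening of known fusion junctions by counting
    uniquely matching junction-spanning reads, fusion-partner graph
    analysis (promiscuous genes, node groups, reciprocal events),
    subgroup-specific differentially methylated CpG calling against
    multiple reference cell populations with genomic-context enrichment,
    a consensus pairwise differential-expression rule, and cross-omic
    integration (methylation-expression overlap, copy-number
    corroboration of fusion loci, alteration co-occurrence). Includes a
    synthetic-data module that generates every input with planted ground
    truth so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
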