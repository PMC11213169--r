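Package: ragscan
Title: RSS Motif Scanning and RAG-Mediated Deletion Classification at
    Structural Variant Breakpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies somatic deletions as putatively RAG-mediated by
    scanning breakpoint flanks for recombination signal sequence (RSS)
    motifs (heptamer, nonamer, and full 12/23-spacer matrices) with
    exact position-weight-matrix p-values, checks excision-circle
    orientation and motif positional decay, resolves deletion junctions
    into non-templated insertion, microhomology or blunt joins, runs
    agnostic k-mer enrichment at breakpoints, and compares patient
    groups with contingency statistics, bootstrap confidence intervals
    and a random-intercept logistic model. A seeded synthetic cohort
    generator with planted motifs makes the whole pipeline runnable and
    testable without access to restricted genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
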