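Package: irmutscan
Title: Characterization of Ionizing-Radiation-Induced Genome-Wide DNA Variants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-variant-calling pipeline for isolating and characterizing
    ionizing-radiation (IR)-induced DNA alterations from whole-genome
    sequencing variant calls. Implements a three-stage filter chain (control
    pool subtraction, depth/genotype-quality thresholds, exact binomial
    sequencing-error test), per-chromosome and per-cytogenetic-band variant
    accumulation, transition/transversion spectra, InDel length and
    repeat/microhomology context signatures with fold-change analysis,
    topologically-associating-domain (TAD) binned density profiles,
    inter-chromosomal translocation deduplication and filtering, and
    SnpEff-style functional-impact summaries. Includes a fully deterministic
    synthetic-data generator (reference, VCFs, band/TAD tables, translocation
    tables) so every stage is testable without external downloads.
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
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
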