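Package: wsstrack
Title: Window-Based SNV Similarity Strain Tracking for Metagenomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Strain-level tracking of gut microbes across samples from
    base-resolution multi-sample variant calls. Computes Window-based SNV
    Similarity (WSS) scores for sample pairs per reference species, applies
    per-species relatedness cut-offs with coverage and depth filters,
    aggregates classifications into cohort-level shared-strain statistics
    (separation-time groups, one-way ANOVA with Tukey HSD), and ships a
    synthetic twin-cohort simulator with known strain-sharing truth so the
    whole pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
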