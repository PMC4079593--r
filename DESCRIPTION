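Package: paleohap
Title: Damage Spectra and Median-Joining Haplotype Networks for Ancient
    Mitochondrial DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating and placing ancient mitochondrial
    amplicon sequences. Provides a circular reference coordinate system with
    insertion-aware alignment-column mapping and gap-exclusion policies,
    per-clonal-group consensus building and reference-anchored variant
    tabulation, nucleotide-misincorporation spectra with composition-bias
    scaling and type-1/type-2 transition classification, a weighted
    median-joining haplotype network builder with quasi-median generation,
    network annotation (per-position mutation frequencies, hotspot detection,
    inverse-frequency weighting, haplogroup-diagnostic motif inference), and
    synthetic-data generators with analytic ground truth for end-to-end
    validation. Results are returned as tibbles with broom-style tidy() and
    glance() methods and ggplot2 autoplot() visualisations.
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
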