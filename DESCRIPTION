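Package: clonotrace
Title: Clonal Phenotypic Plasticity from DNA Barcode Lineage Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying phenotypic plasticity across cancer cell
    clones tracked with random DNA barcodes. Provides synthetic-data
    generators with known ground truth; quality filtering, demultiplexing and
    error-collapsing of barcode amplicon reads; coverage-based library
    complexity, Poisson multiplicity-of-infection and barcode-collision
    calculations; sort-contamination-corrected clone state quantification
    (fraction epithelial, log2 E/M ratios, growth rates, ratio entropy);
    contamination-aware binomial bi-lineage and chi-squared state-bias tests
    with Benjamini-Hochberg correction and permutation tests for stability and
    heritability; sliding-window copy-number inference from single-cell RNA-seq
    with Ward clustering into clones and subtype/stemness scoring; and a
    deterministic clone growth/state-transition simulator for evaluating
    phenotype-selective combination treatment schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
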