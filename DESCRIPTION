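Package: varprior
Title: Scoring, Ranking and Cohort Barcoding of Genetic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotation-driven prioritization of single-nucleotide variants
    and small indels from cohort VCF files. Variants are scored with a
    category-based pathogenicity scheme (nonsense, frameshift, splice,
    missense, ...) refined by conservation and protein-prediction
    adjustments and a two-of-three splice-program consensus rule, summarized
    across a cohort with a per-sample zygosity barcode, passed through a
    configurable quality/frequency filter cascade, and reported as ranked
    per-variant and per-gene tab-separated files. A synthetic-cohort
    simulator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
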