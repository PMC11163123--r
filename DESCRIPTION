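Package: hlaconcord
Title: Consistency Evaluation of HLA Typing Across Sequencing Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the reproducibility of HLA allele calls from
    next-generation sequencing data. Parses IPD-IMGT/HLA-style allele names at
    one-, two- and three-field resolution, scores Mendelian consistency of
    child genotypes against parents in family trios, scores allele-level
    concordance between duplicate typings of the same sample across assays or
    tools, handles the copy-number-variable DRB3/4/5 paralogs as a pooled
    variation unit, and aggregates per-locus results into per-resolution and
    overall consistency percentages. A seeded synthetic-pedigree simulator
    (haplotype frequencies, DRB1-linked DRB3/4/5 carriage, dropout, field
    truncation and mistyping noise) makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
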