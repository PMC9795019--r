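Package: mirbloom
Title: Integrated miRNA-Transcriptome-Degradome Analysis of Flower Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for small-RNA-guided gene
    regulation during flower development: miRNA discovery with stem-loop
    (fold-back) validation and five-group classification against a miRBase-like
    reference, count-based differential expression of miRNAs and mRNAs across
    developmental stages and genotypes, degradome (PARE) cleavage-site
    validation with t-plot categories, and assembly of antagonistic
    miRNA-mRNA(-transcription factor) regulatory modules. Includes a seeded
    synthetic-data generator that plants ground-truth miRNA loci, expression
    effects, cleavage sites and modules so that every stage can be verified
    without external sequencing data, plus 2^-ddCt relative quantification
    utilities for qPCR validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
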