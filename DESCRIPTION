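Package: spliceprone
Title: Identifying Genes and Exons Prone to Splicing Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying how often disease mutations disrupt
    pre-mRNA splicing and for flagging genes and exons that carry more
    splice-site or exonic splicing mutations than expected. Implements
    weighted-random-sampling (Monte Carlo) enrichment envelopes over
    mutation catalogs, quantification of massively parallel splicing
    assay (MaPSy-style) count tables including splicing efficiency,
    allelic imbalance, exonic-splicing-mutation calls and spliceosomal
    complex blockage profiles, hexamer-based exonic splicing regulatory
    (ESR) scoring, position-weight-matrix splice-site models, assembly
    of gene-level genomic feature tables, random-forest and logistic
    regression classification of splicing-mutation-prone genes, and
    population-variant selection analyses stratified by minor allele
    frequency. A synthetic-data module generates every input with known
    ground truth so the full pipeline runs without external resources.
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
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
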