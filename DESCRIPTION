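Package: clonmeth
Title: Methylation Signatures of Clonal Hematopoiesis Driver Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An epigenome-wide association pipeline for linking somatic
    TET2 and DNMT3A mutations to DNA methylation changes in clonal
    hematopoiesis (CHIP), clonal cytopenia (CCUS) and AML cohorts.
    Provides probe-level quality control and cell-type deconvolution for
    methylation arrays, per-CpG twin-aware mixed models and plain linear
    models on M values, a directionality-based significance-threshold
    rule with a top-K fallback, cross-cohort replication tests with a
    chi-squared/Fisher dispatcher, chromatin-state and GREAT-style
    ontology enrichment, ranked motif enrichment by partition-maximized
    Fisher tests, and an elastic-net methylation predictor of mutation
    status. A synthetic-cohort generator with planted, VAF-proportional,
    enhancer-biased effects supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods,
    quadprog,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    lme4,
    glmnet,
    limma
Config/testthat/edition: 3
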