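Package: MitoMeDIP
Title: NUMT-Controlled Mitochondrial Methylome Analysis from MeDIP-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Window-based analysis of mitochondrial DNA methylation from
    MeDIP-seq data with explicit control for nuclear-mitochondrial
    pseudogenes (NUMTs). Implements a three-pass alignment triage that
    retains only reads confidently attributable to the mitochondrial
    genome, 100 bp window quantification (counts, RPKM, log2-RPKM) with a
    coverage filter, per-window differential-methylation statistics
    (paired t tests and a mixed-effects model with Bonferroni control),
    tissue-level clustering and correlation analyses, and a fully seeded
    synthetic MeDIP-seq simulator with planted NUMTs and differentially
    methylated regions for validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Rsamtools,
    lme4,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Sequencing, Alignment, QualityControl
RoxygenNote: 7.3.3
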