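Package: rfiwgas
Title: Whole-Genome Association Tools for Divergent Residual Feed Intake Selection Lines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for whole-genome association studies of
    residual feed intake (RFI) and related production traits (ADFI, ADG,
    back fat, loin muscle area) in divergently selected pig lines. Provides
    PLINK text PED/MAP input and output with SNP quality control, derivation
    of ADG/ADFI/RFI phenotypes through a pedigree-based animal model solved
    by Henderson's mixed-model equations, a drift-controlled between-line
    allele-frequency divergence scan with MAF-binned Z scores and
    Benjamini-Hochberg FDR, a BayesB mixture-model whole-genome regression
    sampler with 1 Mb window variance partitioning and posterior probability
    of association, genomic-control-corrected single-SNP association with
    IBS/MDS stratification diagnostics, and a forward simulator of the
    two-line divergent selection design that supplies ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
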