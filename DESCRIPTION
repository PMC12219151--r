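Package: methlink
Title: Methylation-Expression Region-Gene Linking and Molecular Subtyping
    for Multi-Omic Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for patient-level methylome analysis in
    multi-site tumor cohorts profiled by reduced representation bisulfite
    sequencing (RRBS), RNA-seq and H3K27ac/H3K27me3 histone profiling.
    Provides coverage filtering and variance-based CpG selection, sample
    correlation with intra- versus inter-patient comparison, AR/NE molecular
    subtype classification from signature z-scores, construction of CpG
    regions and histone peak unions, FDR-controlled inference of
    methylation-expression region-gene links conditioned on histone context,
    nomination of methylation-regulated genes, pathway signature scoring, and
    gene-set over-representation. A built-in cohort simulator with planted
    ground truth (patient-specific methylation baselines, subtype expression
    programs, sign-constrained methylation-expression-histone couplings)
    makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    DESeq2,
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
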