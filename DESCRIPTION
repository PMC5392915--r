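Package: methylPanel
Title: Differential DNA Methylation Analysis and Diagnostic CpG Panel
    Discovery for 450K Array Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for tumor versus benign-adjacent differential DNA
    methylation analysis on Illumina Infinium 450K beta values and for
    discovery of small diagnostic CpG panels. Implements probe-design-type
    harmonization of Infinium I and II beta values onto a reduced
    representation bisulfite sequencing (RRBS) scale via quadratic
    calibration, detection masking, missingness and variance filtering,
    empirical-Bayes batch adjustment, a per-CpG random-intercept linear
    mixed model scan with false discovery rate control, CpG island and
    gene-region annotation, transcription-factor binding-site enrichment
    by Fisher's exact test, and exhaustive k-CpG logistic panel search
    with AIC-based size selection, ROC/AUC evaluation and specificity-based
    threshold choice. A truth-annotated synthetic cohort generator provides
    fully reproducible inputs for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    sva,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
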