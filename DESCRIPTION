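Package: blastomics
Title: Transcriptome-Based Quality Assessment of Human Blastocysts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for low-input RNA-seq of biopsied human
    blastocysts (inner cell mass and trophectoderm). Implements clinical
    classification of blastocysts by growth kinetics, Gardner score and
    maternal age with chi-square contingency analysis of pregnancy rates;
    expressed-gene filtering, transcriptome coverage and PCA quality control;
    RNA-based digital karyotyping (sex calls from Y-marker expression and
    X-dosage Z-scores, autosomal gain/loss calls from per-chromosome
    expression Z-scores); and negative-binomial Wald differential expression
    with a Z-score reliability filter and cross-grouping intersection of
    differentially expressed genes. Includes a seeded synthetic-data
    generator that plants karyotype and differential-expression truth at
    biopsy scale, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
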