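Package: phosflow
Title: Phosphoproteomics Quantification, Kinase Activity Inference and
    Drug-Response Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-identification processing of label-free phosphoproteomics
    data (per-sample total normalization, min/10 left-censored imputation,
    technical-replicate averaging, phosphosite and protein roll-ups,
    Student's t differential statistics), set-based activity inference
    (kinase-substrate enrichment, compound-target signature scores,
    transcription-factor activity from summed target-gene z-scores),
    drug-response summarization (area above the dose-viability curve,
    mean-threshold sensitivity labelling, Spearman feature screens, gene
    dependency integration), and a repeated-split classifier of ex vivo
    drug sensitivity combining partial-least-squares feature selection
    with random forests and pooled ROC evaluation. Includes synthetic
    cohort generators with planted ground truth so the whole chain is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
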