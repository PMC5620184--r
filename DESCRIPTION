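Package: bloodmark
Title: Discovery and Validation of Blood Prognostic Biomarkers in
    Dendritic-Cell Vaccination Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for survival-associated biomarker discovery
    and validation from peripheral-blood expression profiles: control-probe
    background adjustment and log2 preprocessing, three-arm candidate
    selection (permutation-based survival and two-class SAM statistics,
    PLS-DA variable importance, fold-change filtering), geNorm-style
    reference-gene identification, delta-Ct relative quantification with
    microarray/qPCR cross-validation, center-normalized ROC and
    Kaplan-Meier evaluation with survival-window sweeps, longitudinal
    expression-change analysis, and anchor-gene correlation ranking with
    preranked gene-set enrichment against blood transcriptional modules.
    Includes a synthetic multi-center cohort generator with planted
    survival-associated genes so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
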