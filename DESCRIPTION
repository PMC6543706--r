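Package: hbnet
Title: Hemoglobin Co-Expression Networks and Expression-Change Biomarkers
    for Ischemic Stroke Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a systems analysis linking anemia and hemoglobin-related
    gene expression to recovery after ischemic stroke. Implements cohort
    baseline comparisons (Welch t, continuity-corrected chi-square, linear
    regression on hemoglobin counts), per-patient two-timepoint differential
    expression with Benjamini-Hochberg control, Pearson co-expression network
    construction over a hemoglobin-related gene panel with seed-neighborhood
    subnetwork extraction (CHB and ECHB layers), Expression Changed Score
    (ECS) biomarker scoring with outcome-concordance classification, and
    delta-delta-Ct qPCR relative quantification with rank-based group tests.
    A seeded synthetic-data generator produces cohort tables, two-timepoint
    expression matrices with planted co-expression modules and fold changes,
    and qPCR plates, so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
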