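Package: episcore
Title: Epi-Score Prediction, Cell-Type Deconvolution and Outcome Modeling
    for Targeted DNA Methylation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling targeted bisulfite sequencing cohorts:
    reference-based cell-type deconvolution from one-vs-all differentially
    methylated marker regions with nonnegative least squares, a pseudoinverse
    multivariate multiple linear regression ("epi score") predictor with
    leave-one-out cross-validation and ROC evaluation, per-CpG
    covariate-adjusted association testing with Benjamini-Hochberg
    correction, epi-score-driven Cox proportional hazards survival analysis,
    moderation analysis of epigenetic age acceleration, and a fully
    ground-truthed synthetic cohort generator for end-to-end validation.
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
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
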