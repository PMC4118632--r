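Package: pulleyquant
Title: Computer-Aided Severity Quantification of A1-Pulley Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies trigger-finger severity from H&E microscopy of the
    A1 pulley. Implements the four-step image pipeline - color and
    illumination normalization, three-class tissue segmentation
    (background / eosinophilic normal / basophilic abnormal), nucleus
    detection with round-versus-spindle shape classification - and the two
    severity parameters Abn-SR (abnormal tissue area ratio) and Abn-NR
    (abnormal nucleus number ratio), together with the study-level
    statistics: one-way ANOVA (raw and summary-statistics forms), LSD
    post-hoc comparisons, Cohen's kappa with interpretation bands,
    inter-rater ICC, Tukey boxplot summaries, and contingency percentage
    tables. A seeded synthetic H&E phantom generator with exact ground
    truth supports testing and whole simulated cohort studies without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    grDevices,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
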