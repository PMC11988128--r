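Package: hanrisk
Title: Hierarchical Attention Networks for Early Cancer Risk Prediction
    from Longitudinal Primary-Care Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An order-sensitive neural pipeline for predicting rare disease
    outcomes (early lung cancer) from longitudinal free-text consultation notes
    in the Dutch SOEP format, optionally fused with structured predictors (age,
    sex, ICPC symptom-code counts). Provides a synthetic longitudinal SOEP-note
    cohort generator with planted signal, cohort windowing and inclusion
    filters, skip-gram word embeddings trained on the training split only,
    hierarchical attention networks (word- and sentence-level BiLSTM encoders
    with attention) trained with a target-replication objective, four ablation
    architectures, and a rare-outcome evaluation protocol with percentile
    bootstrap confidence intervals, paired bootstrap model comparison and
    LOWESS calibration curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
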