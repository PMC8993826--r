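Package: cmaudit
Title: Confusion-Matrix Metrics, Reconstruction and Reporting Audits for
    Binary Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the full suite of binary-classification evaluation
    metrics (accuracy, recall, specificity, precision as PPV/NPV, F1,
    Matthews correlation coefficient, threat score) over confusion-matrix
    counts with explicit undefined-value semantics; reconstructs
    confusion-matrix entries from partially reported metrics and class
    totals at a stated rounding precision; audits published study records
    by flagging confirmed, discrepant and missing metric values; and
    explores prevalence sweeps, biased-classifier baselines, per-class
    evaluation merging and event-to-frame expansion scenarios for medical
    AI studies. Ships machine-readable fixtures of the reported and
    recalculated metric tables of five gastroenterology studies, a
    synthetic study-record generator, CSV/JSON readers and writers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
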