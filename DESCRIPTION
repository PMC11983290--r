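Package: abcscore
Title: Automated Addiction Behaviors Checklist Scoring from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Rule-based clinical natural language processing for identifying
    problematic opioid use in electronic health record notes. Implements an
    automated version of the 20-item Addiction Behaviors Checklist (ABC):
    per-item regular-expression matching with opioid-context, negation and
    false-positive prefix filters, patient-level item vectors and total
    scores, threshold classification, an ICD-code comparator, and an
    evaluation battery (sensitivity, specificity, PPV, NPV, F1, rank AUC,
    recall-precision curves, pairwise phi coefficients, bootstrap confidence
    intervals, score-stratified prevalence tables). Ships a synthetic
    multi-note patient corpus generator with planted ground truth for
    download-free testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
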