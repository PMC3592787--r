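Package: cardioevent
Title: Rule-Based Classification of Coronary and Heart Failure Events from
    Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies acute coronary and heart-failure events (STEMI,
    non-STEMI, systolic heart failure, unstable angina, ambulatory
    presentation, chronic prevalent disease) from structured electronic
    health record extracts: discharge diagnosis codes (ICD-9-CM and IMO
    interface terminology), troponin and BNP laboratory results relative to
    assay upper limits of normal, coded electrocardiogram interpretation
    statements, and echocardiographic ejection fraction.  Implements three
    iterations of a hierarchical phenotyping algorithm, a declarative
    code-matching engine for diagnosis and procedure code sets, validation
    statistics against gold-standard chart-review labels (confusion matrix,
    observed and per-category agreement, Cohen's kappa with asymptotic 95
    percent confidence intervals), and a seeded synthetic-cohort generator
    so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
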