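Package: refluxsap
Title: Symptom-Reflux Association Analysis for Ambulatory Esophageal pH
    Monitoring
Version: 0.1.0
Authors@R:
    person("Esophageal", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for prolonged (48-h, Bravo-style) esophageal
    pH monitoring in gastroesophageal reflux disease. Detects acid reflux
    episodes on a pH trace, computes the six-component DeMeester composite
    acid-exposure score with severity strata, and quantifies the temporal
    association between patient-reported symptoms and reflux using the
    symptom association probability (SAP; Fisher's exact test on consecutive
    2-min windows) together with the symptom index (SI) and symptom
    sensitivity index (SSI). Includes self-contained exact and rank-based
    tests, generators for synthetic pH recordings, symptom logs with tunable
    symptom-reflux coupling, and surgical cohorts, plus cohort-level outcome
    comparisons (SAP-positive vs SAP-negative, symptom counts and types,
    clinical subgroups) for antireflux-surgery populations.
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
RoxygenNote: 7.3.3
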