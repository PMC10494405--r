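Package: painfinder
Title: Rule-Based Identification of Chronic Pain Cohorts in Coded Primary Care Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a chronic-pain case-finding algorithm for coded primary
    care data: four clinical criteria compiled into eight logic rules over
    SNOMED-CT-style diagnosis codes and categorised prescription issues,
    evaluated per patient at a snapshot date. Provides code-list registry
    management, flat-table readers and writers, the rules engine, overall and
    stratified prevalence reporting (age, gender, five-category ethnicity,
    deprivation quintile), and a seed-reproducible synthetic-data generator
    with per-patient ground-truth rule labels for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
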