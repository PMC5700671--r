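Package: natriwas
Title: Dysnatremia Cohort Extraction, PheWAS Confounder Discovery and
    In-Hospital Mortality Models from EHR Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for studying the association between admission
    serum sodium concentration and in-hospital mortality from electronic
    health record (EHR) tables. Provides a synthetic multi-admission EHR
    generator with known ground truth, severity-prioritised one-row-per-patient
    cohort extraction with seven-bin sodium categorisation and an ICD-10
    Charlson comorbidity index, stratified descriptive summaries and
    univariate odds ratios, a phenome-wide association screen (PheWAS) over
    three-character ICD-10 billing codes with Bonferroni correction for
    data-driven confounder discovery, and multivariate logistic models of
    in-hospital death compared by AIC with backward pruning of screen-derived
    covariates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
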