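Package: emrforge
Title: Processing and Validation of Electronic Medical Records for Health
    Services Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A structured pipeline for turning record-level electronic medical
    record (EMR) extracts into analysis-ready visit-level and patient-level
    cohorts. Standardizes mixed-era diagnosis codes (ICD-10-AM to ICD-9-CM
    backward mapping) with a truncation / zero-addition fallback engine and
    full mapping-rate accounting, phenotypes codes to mutually exclusive
    disease categories in the style of the AHRQ Clinical Classification
    Software, applies auditable exclusion criteria, derives disease-complexity
    proxies (Charlson Comorbidity Index, Polypharmacy Score) and socioeconomic
    proxies (housing type from postal code, subsidy status, relative subsidy
    received), and validates the derived measures with Spearman correlations
    under Holm adjustment, negative binomial and multinomial regressions, and
    independence tests. Ships a synthetic multi-table EMR generator with a
    ground-truth ledger so the whole cascade is testable without access to any
    real hospital database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    stats,
    utils,
    MASS,
    nnet,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
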