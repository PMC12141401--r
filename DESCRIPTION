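Package: frailtyfalls
Title: Laboratory Frailty Index and In-Hospital Fall Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to derive deficit-accumulation frailty indices and fall-risk
    scores from hospital admission records and to quantify the incremental
    predictive value of a laboratory-based frailty index (FI-lab) over the
    STRATIFY fall-risk tool. Computes FI-lab from a configurable 35-analyte
    reference panel, a 40-item clinical frailty index, the modified STRATIFY
    score, a polypharmacy score, and the Charlson Comorbidity Index from
    ICD-10 codes; fits the standard suite of logistic regression model
    specifications for in-hospital falls; compares models by DeLong AUROC
    tests, continuous net reclassification improvement, and integrated
    discrimination improvement; and internally validates models by bootstrap
    optimism correction with calibration-slope and calibration-error
    summaries. A synthetic-cohort generator emulating the admission-record
    schema makes the full pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
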