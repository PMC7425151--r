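Package: orthoclaims
Title: Rule-Based Identification of Elective Orthopedic Surgery Indications
    from Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies orthopedic surgical cases from administrative claims
    (ICD-10 diagnosis and CPT procedure codes) into four elective
    procedure/primary-indication combinations: knee arthroplasty for knee
    osteoarthritis, hip arthroplasty for hip osteoarthritis, and lumbar spinal
    surgery for spinal stenosis or herniated disc. Implements a two-step
    computable phenotype (inclusion code matching with ICD-10 hierarchy
    wildcards, an age tie-break for dual-coded spine cases, and
    exclusion-driven demotion of the primary indication), a validation
    framework against gold-standard chart-review labels (two-level sensitivity
    and specificity with exact Clopper-Pearson intervals, predictive-value
    curves over prior probability, Cohen's kappa), and a seeded synthetic
    claims-cohort generator so the full pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
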