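Package: ppisentinel
Title: Rule-Based Surveillance of Proton Pump Inhibitor Gastroprotection
    in Inpatient Medication Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A clinical-decision-support engine that screens longitudinal
    inpatient medication records for missing gastroprotection (patients
    carrying drug-related gastrointestinal bleeding risk without a proton
    pump inhibitor) and for potentially inappropriate proton pump
    inhibitor prescriptions (no drug-related risk factor). Provides a
    configurable ATC-based drug-class knowledge base, a twelve-alert rule
    engine with suppression, hourly surveillance with alert lifecycle and
    automatic termination, discharge-day screening, diagnostic-performance
    and before/after incidence statistics, and a seeded synthetic cohort
    generator with labelled ground-truth incidents for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
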