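Package: ppplines
Title: Treatment-Line Reconstruction and Resource Use from Pharmacy Claims in Palmoplantar Pustulosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for retrospective claims-database studies of palmoplantar
    pustulosis (PPP, ICD-10 L40.3): cohort selection with index date, wash-out
    and continuous-enrollment rules; a line-of-therapy reconstruction algorithm
    with fixed topical/phototherapy exposure windows, DDD-based durations, a
    61-day grace period, overlap arbitration and terminating-event labelling
    (discontinuation, switch, add-on, reduction, no change); a treatment-based
    severity proxy and Charlson comorbidity index; healthcare resource
    utilization and direct-cost metrics per person-month with Kaplan-Meier
    time-to-event estimation; publication-style summary tables; and a synthetic
    claims generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
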