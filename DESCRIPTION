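Package: fireepi
Title: Care-Episode Analytics for Fire-Related Injuries in Hospital
    Discharge Registers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying fire-related injuries (exposure to smoke,
    fire and flames, burns, and combustion gas poisonings) in
    hospital-discharge register extracts. Chains discharge records into
    care episodes with a configurable inter-record gap rule, classifies
    episodes by mechanism of injury from ICD-9/ICD-10 diagnosis and
    external-cause (E-code) ranges, audits the completeness of E-coding by
    year and care-provider type, estimates the minimum clearance period
    separating readmissions from new incident injuries via a
    kernel-smoothed hazard on the backward time scale, and quantifies the
    impact of inclusion criteria on yearly inpatient bed-day totals. A
    synthetic register generator with known ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
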