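Package: carescore
Title: Classify Antenatal Care Trajectories with the CTP Tool and the APNCU Index
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based classification of antenatal (prenatal) care
    trajectories. Implements the Content and Timing of care in Pregnancy
    (CTP) tool, a four-category ordinal classifier based on initiation of
    care, counts of three basic interventions (ultrasound, blood pressure,
    blood screening) against configurable lower/upper ranges, and
    per-trimester timing minima; and the Adequacy of Prenatal Care
    Utilization (APNCU, Kotelchuck) index based on initiation month and the
    ratio of observed to expected visits under a recommended-visit schedule
    (ACOG or Belgian). Includes validated CSV ingestion of visit-level
    records, a calibrated synthetic cohort simulator, cross-tabulation and
    chi-square comparison of the two classifications, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
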