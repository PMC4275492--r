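Package: yapcal
Title: Calibration of Segmented-Day Youth Activity Self-Reports Against
    Accelerometer MVPA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for calibrating segmented-day youth physical-activity
    questionnaires (Youth Activity Profile style instruments) against
    minute-level accelerometer data. Maps accelerometer streams onto a
    weekly school-day window schedule, screens windows with wear-time
    compliance rules, imputes documented nonwear bouts with compendium MET
    values, fits per-item calibration regressions of window percent MVPA on
    age, gender and item score (linear or categorical score encoding),
    aggregates calibrated predictions into school / out-of-school / weekly
    minute composites, and evaluates group-level agreement with two
    one-sided-test (TOST) equivalence procedures. Includes a synthetic
    cohort simulator with age-graded nonwear and monotone (optionally
    plateauing) item-MVPA response links, plus a noncentral-F power routine
    for R-squared-change sample size planning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
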