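Package: physiorisk
Title: Physiological Risk-Condition Classification from Wearable Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying worker risk conditions (balance
    perturbation vs. ordinary physical activity) from multichannel wearable
    recordings: heart rate, heart-rate variability (RMSSD), respiration rate,
    galvanic skin response with tonic/phasic decomposition, skin temperature and
    tri-axial accelerometry. Implements protocol-level formulas (critical heart
    rate, environmental risk coefficient), windowed statistical feature
    extraction, ReliefF feature weighting with incremental optimal-subset
    search, four reference classifiers at fixed hyperparameters, and
    leave-one-subject-out validation with sensor-ablation, environment-split
    and paired signed-rank analyses. Because no public dataset exists for this
    protocol, a synthetic-study generator reproduces the session structure and
    the statistical assumptions of the analysis so every stage is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    signal,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
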