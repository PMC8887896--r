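Package: accsleep
Title: Accelerometry-Based Sleep Scoring and Collective Sleep Analysis for
    Group-Living Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores sleep from burst-sampled triaxial accelerometry on
    wild animals (VeDBA-based sleep-period detection and per-minute
    sleep/wake classification with quality-control filters), infers
    nightly sleep locations and sleep-tree assignments from GPS, tests
    sleep-site fidelity with a Shannon-entropy permutation test,
    quantifies group-level nocturnal synchronization against time-shift
    and night-permutation null models, and builds the epoch-level design
    table for arousal-threshold (wake-contagion) analyses. Includes a
    synthetic biologger-data generator with known ground truth so every
    stage of the pipeline can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    sandwich,
    lmtest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
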