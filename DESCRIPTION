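Package: divebuzz
Title: Predicting Prey-Capture Attempts from Time-Depth Recorder Dive Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate echolocation buzz counts (a proxy for prey
    capture attempts by deep-diving odontocetes) from 1 Hz time-depth
    recorder data. Provides a seeded synthetic biologging-deployment
    generator, foraging-dive detection with descent/bottom/ascent phase
    labelling, fixed-duration dive segmentation, a suite of segment-level
    dive metrics (depth summaries, vertical velocity and acceleration,
    inflections, wiggles, sinuosity), a Poisson mixed-effects model of buzz
    counts per segment with per-individual random intercepts, AIC backward
    selection and Nakagawa-Schielzeth R-squared, and leave-individuals-out
    cross-validated evaluation (AUC, sensitivity, specificity, precision,
    per-dive buzz accounting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
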