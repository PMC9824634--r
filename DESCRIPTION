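Package: msaccid
Title: Person Identification from Fixational Microsaccades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying fixational microsaccades as a behavioural
    biometric. Provides a seeded simulator of fixational eye-movement traces
    (microsaccades, drift, tremor and sensor noise with ground-truth event
    intervals), spectral and Kalman denoising, velocity-threshold and
    chi-square microsaccade detectors, thirteen per-event trajectory
    features (duration, height, self-intersection-aware area, sharpness,
    base length, double-microsaccade ratio and flag, speed and
    pseudo-acceleration summaries, maximal diameter), nonnegative
    quasilinear distance learning by projected steepest descent on a
    within/between-person error ratio, and leave-one-fixation-out person
    identification by greedy assignment with L1 row renormalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
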