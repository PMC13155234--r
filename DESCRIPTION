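Package: gaitdyn
Title: Gait Variability and Local Dynamic Stability from Wearable Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying stride-to-stride gait variability (percent
    coefficient of variation of stride time and stride length) and local dynamic
    stability (short-term local divergence exponent from delay-embedded tri-axial
    lumbar acceleration, Rosenstein-style nearest-neighbour divergence) in cohort
    studies comparing age groups across overground, treadmill and visually cued
    treadmill walking. Includes seeded synthetic generators for stride-parameter
    cohorts, lumbar acceleration signals with known ground truth, and chaotic
    reference systems with a tangent-space (Benettin) Lyapunov oracle; stride event
    detection and bout planning; a 2 x 3 mixed ANOVA inference layer with
    Greenhouse-Geisser correction, Holm-adjusted post hoc contrasts, partial eta
    squared and noncentral-F power; and a visual-cue stepping-target generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
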