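Package: callometry
Title: Acoustic Allometry of Juvenile Crocodilian Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying body-size information in juvenile
    crocodilian vocalizations. Implements the standard bioacoustic
    descriptor set (eight frequency-spectrum descriptors within a 0-5 kHz
    band and five fundamental-frequency contour summaries), an
    autocorrelation pitch tracker with automatic octave-jump repair,
    synthesis of frequency-modulated playback stimuli from printed contour
    constraints, a seeded generator of size-graded synthetic call
    populations with species-specific allometric calibration, principal
    component construction of the two-dimensional acoustic space, linear
    mixed-model likelihood-ratio tests for size coding, allometric
    regression line comparison, and scoring plus mixed-model analysis of
    playback-response experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    multcomp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
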