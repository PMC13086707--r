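Package: PupilKinetics
Title: Superposition-Eye Pupillometry: Camera Calibration, Log-Logistic
    Kinetics and Circadian Rhythm Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for near-infrared pupillometry of insect
    superposition compound eyes. Extracts eye reflectance (integrated
    density over a circular region of interest) from grayscale image
    stacks, corrects for the camera's gamma nonlinearity, fits
    two-parameter log-logistic (Lipetz-type) kinetics to induced pupil
    closing and opening curves, quantifies intrinsic circadian open/closed
    switching in constant darkness, and compares kinetic parameters across
    species, sex and temperature with hierarchical Gaussian GLM selection
    (sequential ANOVA + AIC) and Tukey-adjusted marginal-mean contrasts.
    Includes a seeded synthetic-data generator that emulates the recording
    conditions so the whole pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    emmeans,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'synthetic.R'
    'imaging.R'
    'calibration.R'
    'curves.R'
    'rhythm.R'
    'stats.R'
    'morphometry.R'
    'io.R'
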