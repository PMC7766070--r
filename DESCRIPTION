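Package: ehgcv
Title: Conduction Velocity and Directionality of Uterine EHG Surface Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates conduction-velocity amplitudes and propagation
    directions of uterine electrohysterogram (EHG) surface waves from four
    bipolar signals recorded on a square electrode array, using short-time
    cross-correlation between the upper/lower and left/right signal pairs.
    Provides WFDB record and annotation input/output, zero-phase Butterworth
    band-pass preprocessing for the physiological frequency bands, per-interval
    propagation features (direction and sector percentages, average velocities,
    their ratios) and sample entropy, and a preterm-versus-term classification
    protocol (SMOTE balancing, quadratic discriminant analysis, repeated
    stratified cross-validation). A synthetic planar-wave generator with known
    ground truth supports verification without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    MASS,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
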