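Package: pulseqc
Title: Beat-to-Beat Quality Assessment of Radial Pulse Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for assessing the quality of
    noninvasive radial blood-pressure waveforms acquired by skin-surface
    tonometry. Simulates one-minute beat trains under an appropriate and a
    higher sensor contact pressure, detects pulse feet and segments beats,
    computes forty beat-wise Fourier harmonic indices (amplitude proportions,
    their coefficients of variation, phase angles, and their standard
    deviations), and discriminates high- from low-quality pulses with eight
    supervised classifiers evaluated by threefold cross-validation,
    leave-one-subject-out testing, and subject-grouped hold-out splits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    e1071,
    nnet,
    rpart,
    ranger,
    MASS,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
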