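Package: mispeed
Title: Decoding Motor Imagery Speed from EEG with a Convolutional Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis pipeline for decoding the speed of paced,
    repetitive motor imagery from multichannel EEG. Generates synthetic
    sessions with known ground truth (steady-state movement-related potentials
    at pacing fundamentals and harmonics, occipital steady-state visual evoked
    potentials, condition-dependent alpha/beta event-related
    desynchronization), trains a compact convolution-plus-self-attention
    classifier over four speed classes, and interprets the trained model via
    temporal-kernel frequency responses, spatial patterns, signed
    gradient-weighted class activation maps and class activation topographies.
    Includes current-source-density, Welch power-spectral-density and
    neighbor-bin signal-to-noise analyses of steady-state responses, and
    standard classification metrics with chance-level accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
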