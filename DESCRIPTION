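Package: eegcam
Title: Hopfield Associative-Memory Classification of Driving EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates multichannel driving EEG with left/right turn events,
    preprocesses it with zero-phase Butterworth band-pass filtering and
    amplitude screening, extracts FFT absolute band-power (QEEG) features,
    ranks scalar features by two-sample t statistics, binarizes selected
    features to bipolar patterns, and classifies turn direction with a
    Hebbian Hopfield content-addressable memory.  Includes distortion-recall
    experiments, Monte-Carlo cross-validation, group-level pattern analysis,
    EDF/CSV session input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
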