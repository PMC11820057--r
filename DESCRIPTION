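Package: somnoscore
Title: Automated Vigilance-State Scoring of Rodent Single-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised scoring of wake, NREM sleep and REM sleep from a
    single rodent EEG channel. The pipeline rejects amplitude and
    density-based artifact epochs, detects NREM sleep by majority voting
    over per-band Gaussian mixture clusterings of epoch spectra, and
    isolates REM sleep with a wide-window RMS wake-reduction step,
    stringency voting across theta vs. delta/sigma band combinations,
    a standard-deviation ellipse correction and contextual hypnogram
    rules, optionally refined in a second iteration. A seeded synthetic
    polysomnography generator (hypnogram, EEG and artifact ground truth)
    makes the whole pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mclust,
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    caret,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
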