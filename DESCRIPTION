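Package: dcamnet
Title: Dynamic Convolution Attention Network for EEG Fatigue Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects driver fatigue from multichannel EEG with DCAMNet, a
    lightweight convolutional network whose spectral filters are adapted per
    sample by squeeze-and-excitation kernel attention over a nine-band filter
    bank, followed by spatial convolution and windowed-variance temporal
    attention. Includes zero-phase Butterworth preprocessing and epoching,
    reaction-time (LRT/GRT/ART) and PERCLOS label derivation, subject-mixed
    and leave-one-subject-out evaluation protocols with fold-level paired
    statistics, ablation variants, band-masking and channel-ablation
    analyses, and a synthetic fatigue-EEG generator so the full pipeline is
    testable at desk scale. Training (Adam, step decay, early stopping) and
    the network forward/backward passes are implemented in vectorized R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
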