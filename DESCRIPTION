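Package: actifuse
Title: Multi-Feature Fusion of Image-Reconstructed Accelerometer Signals for Human Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts 10-second tri-axial accelerometer segments (250 Hz) into
    three complementary 64x64 RGB image encodings - an STFT spectrogram with
    horizontally stacked axes, a continuous (unthresholded) recurrence plot
    with one axis per colour channel, and a multi-channel plot that packs the
    integer and decimal digits of min-max-scaled samples into RGB - and
    classifies activities (walking, stair climbing, postural transitions and
    six fall types) with a three-branch convolutional network whose per-branch
    feature vectors are fused by concatenation. Includes a subject-grouped
    synthetic signal simulator, subject-independent splitting, a 1-D
    convolutional baseline, a metric suite (top-1/top-3 accuracy, macro
    precision/recall, ROC AUC, confusion matrices), and evaluation harnesses
    for spectrogram window-size sweeps, reconstruction-method comparison and
    Gaussian-noise robustness sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    pROC,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
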