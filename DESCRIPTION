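Package: fatiguefusion
Title: Multimodal Fatigue Detection from Eye Tracking and ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for detecting operator fatigue in
    screen-based monitoring tasks (remote-tower air traffic control) from
    wearable eye-tracking and single-lead ECG recordings. Implements blink
    repair and I-VT fixation parsing with stationary and transition gaze
    entropy over an AOI grid, sym8 wavelet ECG denoising, Pan-Tompkins
    R-peak detection with ectopic-beat rejection, time- and
    frequency-domain heart-rate-variability features, 60-second window
    segmentation with Samn-Perelli extreme-group labeling, a
    cost-sensitive gradient-boosted classifier with SMOTE oversampling
    and Youden-index threshold moving, leave-one-subject-out evaluation,
    per-subject calibration, and a synthetic physiological cohort
    generator used as a test oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    xgboost,
    caret,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
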