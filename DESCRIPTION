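Package: imuvision
Title: Exercise Classification from Wearable Inertial Sensor Data via Time-Series Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for recognising resistance exercises from a
    body-worn inertial measurement unit (IMU). Recordings are low-pass filtered
    (order-8 Butterworth, 20 Hz), split into single-repetition epochs by peak
    detection and adjacent zero crossings on the dominant gyroscope channel,
    resampled to a fixed length, and rendered as fixed-scale six-panel images
    that a transfer-learning image classifier (frozen convolutional embedding
    backbone plus a retrained softmax layer) labels by exercise. A conventional
    comparator pipeline is included: 18 derived signals, 19 engineered features
    per signal (342 per repetition, including Daubechies-4 wavelet-coefficient
    variances, Higuchi fractal dimension and level-crossing rate) classified by
    a 400-tree random forest under leave-one-subject-out cross-validation. A
    seeded synthetic-data generator emulates repetition-structured recordings
    with class-distinct waveform morphologies so the whole pipeline is testable
    without access to laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    randomForest,
    e1071,
    png,
    jpeg,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
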