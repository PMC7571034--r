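Package: wearhar
Title: Human Activity Recognition from Wearable Stretch and Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end framework for human activity recognition (HAR)
    from a knee-worn stretch sensor and an ankle-worn inertial measurement
    unit. Provides variable-length activity segmentation driven by the
    stretch-sensor derivative, a fixed 120-dimensional feature pipeline
    (FFT of the stretch signal, Haar wavelet approximation coefficients and
    variances of the accelerometer channels, and segment duration), a small
    feed-forward softmax classifier selected by design-space exploration
    under memory constraints, and two online weight-update rules that
    personalize the classifier to unseen users: a policy-gradient update
    driven by correct/wrong feedback and buffered incremental supervised
    learning driven by labeled feedback. A bundled synthetic-signal
    generator produces labeled stretch + accelerometer recordings so the
    whole pipeline can be exercised without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
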