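Package: multigait
Title: Multi-Modality Gait Event Detection, Gait Markers, and Method Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates synchronized three-modality gait recordings
    (foot-mounted and lumbar-mounted inertial sensors and a depth-camera
    skeleton stream) with known ground-truth heel-strike and toe-off events,
    detects those events with sensor-specific signal-processing pipelines
    (zero-phase Butterworth/FIR filtering with peak picking for foot
    gyroscopes, integration plus Gaussian-derivative wavelet differentiation
    for the lumbar accelerometer, second-gradient ankle-depth analysis for
    skeleton data), derives eleven macro and micro spatiotemporal gait
    markers including Weinberg and inverted-pendulum step lengths, and
    quantifies agreement against a reference event stream with mean absolute
    error, Pearson correlation, and Bland-Altman limits of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
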