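Package: ppganf
Title: Noise-Robust Low-Complexity Heart-Rate Estimation from Wrist PPG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streaming heart-rate estimation from wrist-worn photoplethysmography
    (PPG) corrupted by motion artifact. Implements a three-stage pipeline designed
    for low-power wearable hardware: (1) preprocessing (decimation to 25 Hz and
    zero-phase band-pass filtering), (2) motion-artifact reduction with a
    sign-sign normalized adaptive filter driven by the 3-axis accelerometer
    (requiring only M multiplications per sample versus 3M+1 for NLMS), and
    (3) single-tone frequency tracking with an oscillator-based adaptive notch
    filter, including a noise-robust variant that averages recent frequency
    estimates and an IIR band-pass feedback loop that re-filters the desired
    signal around the current heart-rate estimate. Ships Bland-Altman and mean
    absolute error evaluation utilities and a seeded synthetic PPG/accelerometer
    generator so the whole pipeline is testable offline with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
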