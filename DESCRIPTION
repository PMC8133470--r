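Package: gazeclass
Title: Gaze Event Detection and Expertise Classification for High-Speed Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 250 Hz gaze recordings on an equirectangular
    360-degree video frame: a calibrated synthetic trace generator, velocity-threshold
    saccade detection with dispersion-based splitting of fixations and smooth
    pursuits, physiological saccade quality control, extraction of a 46-dimensional
    trial-level feature vector, and a participant-wise resampled support-vector-machine
    protocol for classifying observer expertise, including feature-significance
    screening, most-frequent-feature selection, and a label-permutation control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    e1071,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
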