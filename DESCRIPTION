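Package: eegdecode
Title: Band-Power EEG Decoding of Finger Movements for Prosthesis Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desktop re-implementation of an embedded brain-computer interface
    pipeline that decodes three finger movements (thumb, index finger, fist)
    from 14-channel EEG recorded at 128 Hz. Trials are replayed as 250 ms
    chunks, band-pass filtered to the sensorimotor Mu/Beta band (8-30 Hz) with
    zero-phase order-2 Butterworth filters, summarised per channel as band
    power from Hamming-windowed periodograms, and classified by a two-stage
    binary logistic-regression network whose output maps to prosthesis motor
    commands. A synthetic-EEG generator with class-dependent sensorimotor
    rhythm gains and an optional eye-blink artifact regime makes every stage
    testable without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
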