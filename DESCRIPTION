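Package: engdecode
Title: Grip-Type Decoding from Intrafascicular Nerve Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for decoding grip-type motor
    commands (palmar grasp, pinch grasp, little-finger flexion, rest) from
    multi-channel intrafascicular electroneurogram (ENG) recordings.
    Provides a synthetic-data generator for multi-unit nerve recordings with
    known ground truth, translation-invariant wavelet denoising,
    template-based spike sorting, epoch-wise relative spike-rate features,
    one-against-one support-vector-machine classification with leave-one-out
    validation, exhaustive channel-subset search, cross-day robustness
    evaluation, and normalized firing-rate profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
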