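Package: ssvepDS
Title: Dynamic Stopping for Spatially-Coded SSVEP Brain-Computer Interfaces
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification pipeline for spatially-coded steady-state visual
    evoked potential (SSVEP) brain-computer interfaces with dynamic stopping.
    Implements zero-phase FIR band-pass preprocessing, canonical correlation
    analysis (CCA) spatial filter banks against a sinusoidal reference, linear
    discriminant analysis (LDA) with calibrated class posteriors, and an online
    decision engine that classifies growing chunked EEG windows and stops as
    soon as N consecutive classifications agree with posterior probability at
    least P. Ships evaluation machinery (information transfer rate,
    leave-one-trial-out cross-validation, narrow-band SNR, meta-parameter grid
    searches) and a calibrated synthetic SSVEP EEG generator so the whole
    pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0), MASS, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
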