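Package: attenccnn
Title: Attention-Based Complex-Spectrum Convolutional Networks for SSVEP Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding of steady-state visual evoked potentials (SSVEP) from
    few-channel EEG with a compact convolutional neural network that takes the
    complex spectrum (concatenated real and imaginary FFT parts) of each
    channel as input and reweights convolutional feature maps with
    squeeze-and-excitation attention. Includes joint frequency-phase modulated
    (JFPM) stimulus layouts, a synthetic multi-subject SSVEP generator with
    harmonic structure and 1/f background noise, zero-phase Butterworth
    filtering and epoch segmentation, subject-dependent (10-fold) and
    subject-independent (leave-one-subject-out) evaluation protocols,
    information transfer rate, and a loader for the public 12-class JFPM
    dataset distributed as MAT files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
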