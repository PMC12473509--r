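Package: facephys
Title: Multi-Task Estimation of Cognitive Load, Heart Rate and Respiration
    Rate from Facial Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Camera-based driver monitoring from facial video: fixed-length
    video windows are decomposed into five temporally aligned streams (left
    eye, right eye and mouth crops, normalized facial landmarks, and a remote
    photoplethysmography spatio-temporal map), embedded per frame, encoded by
    a bidirectional selective state-space (Mamba-style) sequence model with
    zero-order-hold discretization, mean-pooled over time and mapped by three
    small multilayer perceptron heads to a binary cognitive-load probability
    and heart-rate/respiration-rate regressions.  Training couples a truncated
    cross-entropy with smooth-L1 losses under a sigmoid-ramp multi-task weight
    schedule.  Includes a synthetic physiological-video generator with
    controllable heart-rate, respiration and blink structure so the whole
    pipeline can be exercised and verified without restricted driving corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
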