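Package: errpipe
Title: Simulation and Riemannian Tangent-Space Classification of Tactile
    Error-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting error-related potentials
    (ErrPs) evoked by erroneous movements of an actuated arm orthosis. The
    package simulates the experimental session structure (32-movement sets
    with 6 planted errors), subject button-press behaviour, and continuous
    multichannel EEG with planted ErrP and motor-potential components; reads
    and writes a BrainVision-style header/marker/binary file triad; performs
    epoch extraction, behavioural exclusion, zero-meaning, decimation and
    band-pass filtering; extracts features through an xDAWN spatial filter,
    extended epochs, Ledoit-Wolf shrinkage covariance, Frechet (geometric)
    mean, tangent-space projection and Mandel vectorization; and evaluates a
    class-weighted linear support-vector classifier with nested stratified
    cross-validation, balanced-accuracy metrics and cross-scenario transfer
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    signal,
    e1071,
    ggplot2,
    generics,
    jsonlite,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
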