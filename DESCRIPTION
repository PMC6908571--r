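Package: rotdyn
Title: Rotational Dynamics Diagnostics for Neuronal Population PETHs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to dissect apparent rotational dynamics in neuronal
    population recordings. Provides a simulator of condition-structured
    peri-event time histogram (PETH) populations with controllable temporal
    sequences of Gaussian response peaks, PETH peak-ordering and
    subpopulation analysis, surrogate perturbations (per-neuron condition
    shuffling and forward time shifts with constant padding), a
    skew-symmetric least-squares dynamical fit on PCA-reduced state
    trajectories (jPCA) with ill-conditioning diagnostics, and readout of
    arbitrary Lissajous target curves by multiple linear regression with
    train/test condition splits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
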