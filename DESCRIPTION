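Package: iksim
Title: Markov Gating Models and Voltage-Clamp Analysis for IKs Channel
    Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates macroscopic slow delayed-rectifier potassium (IKs,
    Kv7.1/KCNE1) currents from voltage-dependent Markov gating schemes,
    including closed-state stabilization by adamantane-class gating
    modifiers and an explicit ligand-binding extension for wash-in
    kinetics.  Ships the standard two-electrode voltage-clamp protocol
    presets, synthesizes noisy recordings and Hill-distributed
    concentration-response tables for pipeline testing, and fits the four
    curve families of routine electrophysiology analysis: Hill
    concentration-response, Boltzmann activation, single-exponential
    kinetics, and log-linear wash-in slopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
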