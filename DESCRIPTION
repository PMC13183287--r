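Package: jansenrit
Title: Multi-Frequency Jansen-Rit Whole-Brain Modelling with Homeostatic
    Inhibitory Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates whole-brain neural mass dynamics in which every region
    is a two-subpopulation (alpha- and gamma-tuned) Jansen-Rit cortical column
    with homeostatic inhibitory synaptic plasticity that clamps pyramidal
    firing rates around a target value. Provides the stochastic network
    integrator (Euler-Maruyama, 1 ms), a Balloon-Windkessel haemodynamic
    forward model, spectral observables (Bessel band-pass filtering, Hilbert
    envelopes, Welch power spectra, relative band power), amplitude-envelope
    and BOLD functional connectivity, goodness-of-fit metrics (structural
    similarity, Clarkson similarity, Cohen's d) with grid-sweep orchestration,
    synthetic connectome and signal generators, and a numerical bifurcation
    toolkit (equilibrium and limit-cycle continuation with Floquet
    multipliers) for the single-node model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
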