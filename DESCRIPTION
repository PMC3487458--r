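Package: icsim
Title: Conductance-Based Simulation of Inferior Colliculus Responses to
    Amplitude-Modulated Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-compartment Hodgkin-Huxley style models of inferior
    colliculus (IC) neurons driven by stochastic afferent spike trains whose
    rate and synchrony follow specified modulation transfer functions (MTFs).
    Includes six intrinsic firing-type presets, AMPA/NMDA/GABA-A synaptic
    conductances with interval-dependent short-term depression, a von Mises
    phase-locked spike-train generator, vector-strength and Rayleigh-statistic
    analysis with rate/temporal MTF shape classification, and scenario runners
    for input-convergence recipes, synaptic-plasticity ablations, parameter
    sweeps, and aging scenarios in which GABA-A inhibition is reduced.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
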