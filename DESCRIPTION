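Package: vclamp
Title: Virtual Electrophysiology of Conductance-Based Hippocampal Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of three-compartment conductance-based model
    neurons representing regular firing, delayed firing and stuttering
    hippocampal phenotypes, and compares their intrinsic excitability under two
    stimulation protocols: conventional current steps and simulated synaptic
    bombardment delivered through a conductance-clamp (dynamic clamp) rate law
    driven by Poissonian presynaptic voltage waveforms. Provides
    Hodgkin-Huxley-type gating kinetics with sigmoid steady states and
    bell-shaped time constants, a fixed-step exponential-Euler integrator with
    a compiled inner loop, virtual pharmacology (conductance removal), kinetic
    parameter sweeps of the Kir and D-type potassium currents, a leaky
    integrate-and-fire control population, and extraction of standard
    excitability measures (rheobase, input-output curves, cumulative spike
    counts, first-spike latency with Belehradek fits, input resistance, sag).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
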