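Package: neurogain
Title: Gain Analysis of a Conductance-Based Tonically Firing Model Neuron
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a single-compartment Hodgkin-Huxley-type model
    neuron with seven voltage-gated channels, passive conductances and an
    intracellular calcium pool, and analyses how ion-channel expression
    shapes neuronal gain. Provides tonic and Poisson-interval synaptic
    stimulus generators, spike and firing-pattern metrics, current-
    frequency tuning curves with spline-based maximal-gain extraction,
    conductance sweeps and per-channel gain-impact estimates, and
    mechanistic analyses: the dynamic voltage window, activation-
    steepness correlations, per-spike average currents, current-voltage
    loops with rate-matched voltage-occupancy histograms, calcium/KCa
    coupling manipulations, and activation-curve shifting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
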