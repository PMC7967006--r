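Package: vestsim
Title: Galvanic Stimulation Responses of a Hair-Cell / Vestibular-Afferent Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Conductance-based point-neuron simulation of an irregular
    vestibular afferent driven by stochastic excitatory postsynaptic
    currents (EPSCs), with galvanic (direct-current) vestibular
    stimulation (GVS) delivered both to the axon and to a
    phenomenological fast/slow hair-cell adaptation pathway that
    modulates EPSC arrival rate. Provides stimulus-protocol builders,
    a seeded EPSC event generator, an exponential-Euler integrator for
    the sodium / high-voltage potassium / low-voltage potassium / leak
    axon model, hair-cell adaptation filters with closed-form transfer
    functions, spike-train statistics (firing rate, interspike-interval
    regularity, rate-versus-current slopes with bootstrap confidence
    intervals, sinusoidal half-cycle gain and phase, cluster-based
    permutation comparison of rate traces), and experiment runners that
    reproduce the characteristic afferent responses to galvanic
    stimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
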