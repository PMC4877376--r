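Package: dasynergy
Title: AMPA/NMDA Receptor Synergy in Dopaminergic Neuron Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses two models of the midbrain dopaminergic
    neuron under tonic AMPA and NMDA receptor co-activation: a minimal
    FitzHugh-Nagumo-type oscillator whose recovery nonlinearity is an
    SK-type calcium-activated potassium current, and a conductance-based
    model with L-type calcium, SK, ERG and instantaneous potassium
    currents. Provides adaptive ODE integration with threshold-crossing
    spike detection, steady-state firing-frequency estimation and regime
    classification, phase-plane tools for the planar model (nullclines,
    equilibria, linear stability, Andronov-Hopf boundary tracing), and
    one- and two-parameter sweeps over the synaptic conductance plane
    with synergy summaries and conductance-ratio profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
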