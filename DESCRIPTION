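Package: slotsim
Title: Receptor-Slot Competition Dynamics of Synaptic Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and analysis toolkit for the competition of synapses
    for a shared dendritic pool of neurotransmitter receptors. Synaptic
    efficacy is the number of receptors bound to postsynaptic slots; mass
    action binding/unbinding to slots and slow receptor externalization and
    internalization couple all synapses through the pool. The package
    provides the deterministic mass-action equations with event schedules
    and time-varying rates, closed-form steady states on the fast and slow
    timescales with sensitivity analysis, a reduced one-dimensional model of
    receptor accumulation, an exact Gillespie simulation of the integer
    model, plasticity protocols (pool steps, slot steps, waveform-driven
    long-term potentiation), and coefficient-of-variation fluctuation
    analysis with power-law fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
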