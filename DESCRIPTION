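Package: spinesim
Title: Kinetic Simulation of Glutamatergic Signaling in a CA1 Dendritic Spine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of glutamatergic transmission at a
    hippocampal CA1 dendritic spine. The spine is represented by four
    well-mixed compartments (synaptic cleft, postsynaptic density, cytosol
    and endoplasmic reticulum) coupled by pumps, channels and diffusive
    exchange. The package provides a generic compartmental reaction-network
    core with ordinary-differential-equation assembly, a radial
    glutamate-diffusion model of the cleft with generic transporter uptake, a
    cubic ternary-complex model of group-I metabotropic glutamate receptor
    (mGluRI) activation coupled to the Gq/PLC/IP3 cascade, a De Young-Keizer
    type IP3-receptor gating model with ER calcium release, SERCA/PMCA/NCX
    calcium homeostasis with cytosolic buffers, Markov AMPA and NMDA receptor
    schemes, a stimulation-protocol library (single release, bursts,
    theta-burst and tetanic trains), and an analysis layer (Riemann-sum AUC,
    Hill/EC50 and mono-exponential decay fitting, receptor-contribution
    decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    MASS,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
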