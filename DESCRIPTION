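Package: neurodyn
Title: Conductance-Based Neuron and Network Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction, simulation and in-silico characterization of
    conductance-based neuron and network models. Models are hierarchical,
    named trees of compartments, ion-channel populations (Hodgkin-Huxley
    gating formalism), graded chemical and electrical synapses, and
    intracellular mechanisms (calcium buffering with Nernst reversal,
    calcium-dependent integral control of conductance densities).
    Fixed-step integrators include exponential Euler, classical
    Runge-Kutta, and an implicit Crank-Nicolson scheme for unbranched
    cables, plus a voltage-clamp mode. A protocol layer provides f-I
    curves, activation-curve recovery from simulated voltage clamp,
    spike and burst detection, dominant-current labeling, trace-similarity
    costs, and parameter sweeps. Models serialize to flat vectors for
    snapshots, bit-exact resets, and MD5 hashing of structure and state.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    digest,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
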