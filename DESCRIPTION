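Package: flysnn
Title: Data-Driven Spiking Network Model of the Drosophila Olfactory System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Drosophila olfactory nervous system (antennal lobe
    and mushroom body) as a lightweight spiking neuronal network built from
    connectome-style neuron and edge tables. Neurons follow the piecewise
    quadratic neuron (PQN) model in single-compartment, two-compartment, and
    homeostatic projection-neuron variants; synapses use a qualitative kinetic
    model with reward-driven long-term depression of Kenyon-cell to MBON-alpha1
    weights. Includes Poisson olfactory receptor neuron input driven by an
    odorant response table, a calibrated synthetic topology generator,
    in-silico experiments (associative learning success rate, virtual local
    field potentials and Welch power spectra, local-neuron inactivation,
    windowed firing-rate time courses), and a bit-accurate 18-bit fixed-point
    arithmetic backend mirroring digital hardware implementations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
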