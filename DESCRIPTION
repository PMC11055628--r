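Package: snncolearn
Title: Co-Learning Synaptic Weights, Delays and Neuronal Adaptation in
    Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-time simulation and surrogate-gradient training of
    feed-forward spiking neural networks in which synaptic weights,
    per-synapse propagation delays and per-neuron adaptation parameters
    (the constrained adaptive leaky integrate-and-fire, cAdLIF, neuron)
    are optimized jointly by backpropagation-through-time. Includes a
    temporal-context pseudo-gradient rule for delay learning, a
    single-neuron adaptation regime mapper that motivates the parameter
    constraints, a synthetic spike-lag task generator with known
    ground-truth delays, event-stream binning utilities, and
    command-style entry points for reproducible experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
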