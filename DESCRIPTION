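Package: calcitron
Title: Calcium-Controlled Synaptic Plasticity in a Perceptron-Like Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulator for the calcitron, a perceptron-like neuron whose
    synaptic weight updates are driven by per-spine calcium summed from four
    sources: local presynaptic input, heterosynaptic depolarization, the
    backpropagating action potential, and an external supervisory signal.
    Implements the linear and fixed-point/learning-rate (FPLR) calcium
    plasticity rules with an optional post-potentiative neutral zone,
    enumeration and synthesis of the pre/post learning rules implementable
    by calcium control, supervisory microcircuits (label, critic, and
    homeostatic disinhibition), seeded experiment protocols (Hebbian and
    anti-Hebbian learning, heterosynaptic pattern recognition, one-shot
    flip-flop place fields, homeostatic rate control, perceptron learning),
    and a command-line interface with CSV/JSON trace export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
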