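Package: spikexor
Title: Noise-Driven Adaptability of a Minimal Spiking XOR Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clock-driven simulation of a five-neuron leaky integrate-and-fire
    XOR circuit with exponential postsynaptic currents and Tsodyks-Markram
    short-term plasticity, together with a matched 2-2-1 ReLU circuit.
    Generates additive white, input-scaled multiplicative and
    Ornstein-Uhlenbeck noise currents (common or independent across the two
    input neurons), evaluates analog XOR accuracy as a function of the
    decision boundary, and provides grid-search and noise-sweep drivers to
    study stochastic resonance at sub-optimal decision boundaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, graphics, utils, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
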