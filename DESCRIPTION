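Package: vmhswitch
Title: Spiking Circuit Models of the Ventromedial Hypothalamus Assessment-Flight Switch
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a family of spiking circuit models of the ventromedial
    hypothalamus (VMH): excitatory Assessment and Flight core populations driven
    by amygdala sensory input and coupled through inhibitory shell feedback, with
    optional Tsodyks-Markram short-term plasticity and slow post-inhibitory
    rebound excitation. Provides trial-structured inhomogeneous Poisson stimulus
    generation, an exact-exponential leaky integrate-and-fire engine with
    Bernoulli synapses, PSTH-based switch-onset detection and five-criterion
    trial classification (Switch / Intermittent / None), switch-triggered
    averaging, latency-versus-slope thresholding analysis, and parameter-space
    sweeps with PCA projection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
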