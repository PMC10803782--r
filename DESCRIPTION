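Package: connrc
Title: Connectome-Informed Reservoir Computing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements biological connectivity matrices (connectomes) as
    fixed recurrent reservoirs for reservoir computing. Provides loading,
    validation and transformation of weighted connectomes, degree-preserving
    rewired null ensembles, generators for supervised cognitive-task
    datasets (perceptual decision making, context-dependent decision making,
    memory capacity), discrete-time echo-state simulation with selectable
    activation functions, a leaky-integrate-and-fire spiking reservoir with
    double-exponential synaptic filtering, regularized linear readouts,
    classification and memory-capacity metrics, and an orchestration layer
    that sweeps the spectral radius across dynamical regimes, compares
    empirical networks against rewired nulls, and stratifies readout modules
    by functional system.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
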