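Package: proteospread
Title: Simulation of Pathogenic Protein Accumulation, Spread and Toxicity in
    Cortical Column Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compartmental simulator of prion-like protein pathology on a
    multi-column spiking neural network. Each neuron is three cylindrical
    sections (dendrite, soma, axon) carrying normal and pathogenic protein
    concentrations subject to production, templated misfolding, adaptive
    clearance, passive diffusion on the synapse graph, active axonal
    transport and spike-triggered synaptic transfer. Protein burden drives
    neuronal toxicity, firing-threshold shifts and cellular death. The
    package ships the breakdown-pattern metrics (synaptic strength gradient
    and distance-to-seed survival regressions, Dice-based death-order
    convergence, damage asymmetry, time to network breakdown), a
    particle-level Brownian misfolding simulation used to validate the
    product-form misfolding law, a single-compartment equilibrium model and
    a factorial sweep harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'proteospread-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'kinetics.R'
    'toxicity.R'
    'network.R'
    'spiking.R'
    'spread.R'
    'engine.R'
    'io.R'
    'methods.R'
    'metrics.R'
    'particlebox.R'
    'rng.R'
    'sweep.R'
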