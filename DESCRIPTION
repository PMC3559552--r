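Package: endoabm
Title: Agent-Based Simulation of Human Endotoxemia with Circadian Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic, multi-compartment agent-based model of the acute
    inflammatory response to bacterial endotoxin (LPS) in a population of
    circulating leukocytes. Molecules (LPS, TLR4, the NFkB/IkB/IKK signalling
    proxy, aggregate pro- and anti-inflammatory cytokines, bio-energetic
    proteins, cortisol, melatonin and their receptors) are discrete lattice
    agents performing Moore-neighbourhood random walks across plasma, brain,
    cytoplasm and nucleus compartments, interacting by collision rules and
    producing new molecules by per-residency Bernoulli draws. The package
    includes the trend-analysis calibration of production probabilities to
    homeostasis, the time-scale search that maps simulated response timing to
    in vivo observations, population statistics (Shannon-entropy
    variability-based fitness, synchronization, sensitivity coefficients,
    effective LPS concentration) and reproducible experiment runners for
    homeostasis, LPS challenges and time-of-day vulnerability sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    SummarizedExperiment,
    S4Vectors,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'world.R'
    'simulate.R'
    'statistics.R'
    'calibration.R'
    'experiments.R'
    'RcppExports.R'
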