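Package: maxcaliber
Title: Constraining Recurrent Generative Models of Molecular Time Series by
    Maximum Caliber Path Reweighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns a generative path-probability model of a discretized
    one-dimensional molecular time series with an embedding + LSTM + softmax
    recurrent network, and imposes arbitrary thermodynamic or kinetic
    constraints on the generated path ensemble through Maximum Caliber
    reweighting: solve the Lagrange-multiplier shift for a target
    ensemble-averaged observable, subsample trajectories with exponentially
    tilted weights, and retrain the generator on the biased subset.
    Includes analytic Markov-chain oracles (kernel estimation, closed-form
    kernel reweighting, stationary analysis, eigenspectra, exhaustive path
    enumeration), path observables (transition rates, population symmetry,
    deviation from exponential decay), and synthetic trajectory generators
    for a three-state Markov chain, an asymmetric bistable order parameter,
    and quantum-jump photon-number records of a leaky atom-cavity system
    with a dense Lindblad integrator as reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
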