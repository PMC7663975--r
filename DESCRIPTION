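Package: ecoevosim
Title: Eco-Evolutionary Dynamics of Competing Communities Under Directional Environmental Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates communities of phenotypic species evolving by adaptive
    dynamics in D-dimensional trait space while the optimum of the carrying
    capacity moves at a constant rate, modelling directional environmental
    change. Provides the logistic competition model with an asymmetric
    Gaussian competition kernel, ecological equilibration with extinction
    pruning, explicit-Euler adaptive dynamics of phenotypes, a split/merge
    diversification scheme, closed-form single-species analytics of the
    speed-lag trade-off, a replicate sweep protocol over rates of
    environmental change with survivor-averaged statistics and the extinction
    threshold, and an individual-based Gillespie counterpart with clustering
    of individuals into species.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
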