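Package: adaptMC3
Title: Adaptive Metropolis-Coupled MCMC with Automatic Temperature Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A Metropolis-coupled MCMC (parallel tempering) engine in which
    the spacing of the heated-chain temperature ladder is tuned during the
    run toward a target swap-acceptance probability. Provides incremental and
    beta-quantile temperature ladders, locally aware adaptive spacing updates,
    random-pair and neighbour swap moves, seed-deterministic chain execution
    with checkpoint/resume, a self-contained Bayesian phylogenetic testbed
    (Jukes-Cantor likelihood via Felsenstein pruning, constant-size Kingman
    coalescent prior, standard tree proposals, coalescent and sequence
    simulators), and the convergence diagnostics used to evaluate tempered
    samplers (autocorrelation-based effective sample size, two-sample
    Kolmogorov-Smirnov distance, clade-support comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
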