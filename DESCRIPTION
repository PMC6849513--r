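Package: cuecanal
Title: Cross-Situational Word Learning from Multiple Unreliable Cues
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates cross-situational word learning in a recurrent
    hub-and-spoke neural network trained with backpropagation through
    time. Learning events pair two spoken word forms with two visual
    referents, only one of which is named; prosodic, gestural and
    distributional cues mark the target with configurable reliability.
    The package provides the pseudopattern lexicon generator, the trial
    constructor, the network and its gradient machinery, an experiment
    harness measuring speed to a learning criterion and post-training
    robustness when cues are withdrawn, repeated-measures analyses of
    the resulting outcome tables, and a command-line style driver for
    reproducible condition grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
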