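Package: periodicHMM
Title: Hidden Markov Movement Models with Periodic Transition Probabilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits hidden Markov and finite mixture models to animal movement
    series (hourly step lengths and turning angles), allowing the state
    transition probabilities to vary with hour of day through a
    multinomial-logit link with block, quadratic, sinusoidal or fully hourly
    structure.  Includes derivation of step/turn series from GPS fix tables,
    likelihood-based fitting with multi-start quasi-Newton optimisation,
    Viterbi decoding, BIC-driven selection of the number of movement states,
    a generative simulator with GPS-noise injection, a state-count recovery
    experiment, and diagnostics based on hourly step-length profiles and
    step-length autocorrelation functions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
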