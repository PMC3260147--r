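Package: ampf
Title: Adaptive Memory-Prediction Framework Agents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hierarchies of memory-prediction units built from Kohonen
    self-organizing maps (spatial pooling), recurrent SOMs (temporal
    pooling) and first- or variable-order Markov predictors, extended with
    reward-correlator relays that bias feed-back messages toward states
    whose actions correlate with increasing reward. Includes seeded
    synthetic environments (drifting colours, moving lines, letter-image
    word streams, a rocks-paper-scissors opponent), a demo runner with CSV
    metrics and JSON checkpoints, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
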