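Package: schemascore
Title: Automatic Schema Scoring of Cognitive-Therapy Thought Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring thought-record utterances against nine
    maladaptive cognitive schemas on an ordinal 0-3 scale. Implements the
    averaged normalized word-embedding utterance representation,
    distribution-matched train/validation/test splitting, k-nearest-neighbour
    and support-vector scoring models, bidirectional LSTM scoring networks
    with a median-of-restarts selection protocol, rank-correlation evaluation
    with bootstrap confidence intervals and weighted Cohen's kappa, and the
    downstream multilevel and regression analyses linking scoring accuracy to
    downward-arrow depth, closed-to-open schema transfer, and participant
    mental-health scales. A seed-deterministic synthetic corpus generator
    with known ground truth supports testing every stage offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
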