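Package: seqstrat
Title: Search-Strategy Tracking in Sequential Binary Decision Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for inferring search strategies from trial-by-trial
    behavioral logs of a binary-decision-tree (BDT) task. Implements the
    task environment (tree geometry, concept-icon mapping, session
    protocol), four hierarchically ordered strategy automata (random,
    spatial, generative, discriminative) with formal domain-of-action and
    knowledge-update rules, a hidden-Markov-style behavioral model with
    vote-based transition probabilities under a Gaussian observation
    window and constrained-Viterbi weight updates, a Mixture-of-Experts
    next-choice predictor with exploration/exploitation scoring, and a
    synthetic-agent simulator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
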