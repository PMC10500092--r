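Package: mttree
Title: Multi-Target Decision Trees for Mixed Clinical Endpoints
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Greedy and lookahead induction of a single interpretable decision
    tree that explains several clinical endpoints of heterogeneous types
    (continuous, categorical, count/event-rate, and censored time-to-event)
    simultaneously. Supports per-target weights, seven multi-target split
    evaluation criteria, constraint-based pre-pruning, grid-search k-fold
    cross-validated tuning, held-out evaluation, text/DOT tree rendering, a
    planted-subgroup synthetic data generator, and a command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
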