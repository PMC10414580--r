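Package: medtric
Title: Clinically Aligned Evaluation of Multi-Label Diagnostic Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scoring of multi-label computational diagnostic systems with a
    clinically aligned metric that orders errors by clinical severity (wrong
    diagnosis worse than missed diagnosis worse than over-diagnosis), supports
    per-diagnosis significance weights, partial credit for clinically similar
    over-calls, penalties for contradictory predictions, and is invariant to
    the class prevalence of the evaluation set. Also provides the standard
    label-based and example-based multi-label metrics (micro/macro precision,
    recall, F1, Hamming loss, subset accuracy) and the weighted-accuracy
    challenge metric used in cardiology screening benchmarks, plus Monte-Carlo
    stress tests that measure how often a metric respects clinical error
    ordering and how much it drifts when class prevalence shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
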