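Package: randser
Title: Algorithmic Complexity of Human-Generated Binary Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the randomness of human-generated binary
    sequences with the Coding Theorem and Block Decomposition methods,
    including overall and rolling-window normalized complexity measures.
    Implements a working-memory account of random-like series generation
    (a bounded storage buffer, schema-driven proposals, a complexity-based
    randomness judgment, and fatigue that depends on storage load), scoring
    of randomness-comparison and complex-span tasks, participant exclusion
    filters, and the accompanying statistical layer: rank-sum tests,
    inverse-variance weighted least squares, and a penalized B-spline mixed
    trend model with a condition-difference smooth and permutation
    inference. Ships a binary Coding-Theorem lookup table computed by an
    exhaustive enumeration of small (4-state, 2-symbol) Turing machines;
    the enumerator itself is part of the package.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
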