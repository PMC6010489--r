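Package: cuewalk
Title: Step-Length Distributions of Cue-Driven Search Walks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing animal search paths as collections of
    straight steps whose length distribution reflects the spatial structure
    of substrate micro-cues. Provides truncated step-length distribution
    families (exponential, bi-exponential, stretched exponential,
    generalized stretched exponential with the fractal-dimension constraint,
    and power law) with maximum-likelihood fitting, AICc-based model
    selection and Akaike weights; trajectory segmentation by turn-angle and
    minimum-run criteria; generators for uniform and quadrant-retention
    fractal cue fields with box-counting dimension estimation; and an
    automaton walker simulator whose free paths realize the predicted
    encounter statistics. Includes an end-to-end study pipeline
    (simulate, segment, fit, compare, report).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
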