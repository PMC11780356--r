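Package: trioquant
Title: Quantification of Projection-Specific Rabies Tracing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification and statistics for projection-specific
    (TRIO-style) monosynaptic rabies tracing of cortico-thalamo-cortical
    circuits. Provides landmark-based affine registration and virtual
    flattening of serially sectioned cortex onto an in-vivo visual-area
    map, assignment of labelled input neurons to cortical areas and
    layers, input-fraction and spatial-density summaries (hexagonal
    binning, distance-to-target kernel densities), a shuffled-target
    permutation framework for testing reciprocity and antireciprocity of
    corticothalamic inputs, polar-axis analysis of superior-colliculus
    inputs, and a seeded synthetic-data generator that emulates the
    statistical structure of such experiments for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
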