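Package: mdenergy
Title: Modular Dirichlet Energy Analysis of Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Graph-signal-processing toolkit for localising, in time, the
    drivers of functional-connectivity differences in multichannel
    electrophysiological recordings. Builds weighted correlation graphs over
    long task epochs, decomposes the Dirichlet energy of short-window graph
    signals over pre-defined electrode modules (modular and between-module
    Dirichlet energy), and runs a two-level paired-test inference pipeline
    with hierarchical false-discovery-rate control. Includes a synthetic
    event-related-potential generator with controllable modular correlation
    structure and window-localised condition effects for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
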