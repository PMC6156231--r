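Package: tectogain
Title: Analysis of Collicular Gain Modulation of Cortical Size Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for analysing extracellular recordings from the mouse
    early visual system under interleaved optogenetic manipulation: threshold
    spike detection, evoked-response and tuning-curve extraction, surround
    suppression / orientation / direction selectivity indices, spike-triggered
    receptive-field mapping, a contrast-matching procedure, and a
    normality-gated statistical test battery. Includes a mechanistic
    synthetic-data generator for a tecto-geniculo-cortical circuit in which a
    size-independent geniculate gain change produces a size-dependent
    cortical effect through divisive normalization, used for closed-loop
    validation of every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
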