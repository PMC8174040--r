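Package: planhorizon
Title: Planning-Horizon Analysis for Discrete Sequence Production Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for viewing-window discrete sequence production (DSP)
    experiments in which participants produce 14-press finger sequences while
    only a fixed number of upcoming digits is visible. Provides a generative
    simulator of complete experiments (trial tables, force traces, eye
    samples), force-threshold keypress detection, reaction-time, movement-time
    and interpress-interval computation, an exponential saturation model of
    movement time against viewing-window size with an effective planning
    horizon statistic, decomposition of interpress intervals into preplanned
    and online-planned categories, gaze-to-digit mapping at keypress times,
    and within-subject repeated-measures statistics, together with an
    end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
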