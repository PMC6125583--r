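Package: laminarifc
Title: Cortical-Depth Tonotopy and Feature-Dependent Intrinsic Functional
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for laminar (cortical-depth resolved)
    phase-encoded auditory fMRI. Maps tonotopy and spectral tuning width
    from chirp-stimulus BOLD runs, parcellates the auditory sheet into a
    narrowly tuned core and a noncore region, quantifies inter- and
    intra-subject variability of the feature maps, and measures
    feature-dependent intrinsic functional connectivity (iFC) on model
    residuals, summarised per depth and region by the decay constant of
    an exponential fit.  A synthetic-data generator with known ground
    truth (tonotopic gradients, tuning widths, exponential residual
    covariance) makes every stage testable by parameter recovery.
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
    optparse,
    yaml
Config/testthat/edition: 3
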