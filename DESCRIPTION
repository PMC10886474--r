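Package: afmring
Title: Ringing-Mode AFM Force-Curve Processing and Cell-Surface Texture
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Tools for sub-resonance (HybriD-style) atomic force microscopy
    force-curve processing with Ringing-mode extraction of restored and
    viscoelastic adhesion, cantilever thermal calibration (deflection
    sensitivity and PSD/equipartition spring constant), areal surface
    texture parameters in the ISO 25178-2 tradition including the
    2D-Fourier spatial indices Stdi, Srwi and Shw, and statistical
    screening of parameter trends across an activation time course.
    Includes a fully synthetic data generator (force cycles, thermal
    cantilever noise, neutrophil-like surface maps with a latent
    activation level) so that every stage of the pipeline is testable
    without instrument data, plus Gwyddion Simple Field and CSV map I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
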