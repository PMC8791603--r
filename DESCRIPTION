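Package: cortexpulse
Title: Kymograph Analysis of Pulsatile Cortical Myosin and Posterior
    Polarity Crescents in the Drosophila Oocyte
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pulsatile non-muscle myosin-II foci along the oocyte
    cortex from calibrated time-lapse fluorescence movies.  A user-traced
    cortical polyline anchored at the posterior pole is resampled to uniform
    arc length, a position-by-time kymograph is extracted by band-averaged
    bilinear sampling, strong-intensity pixels are thresholded (robust
    median + k*MAD or Otsu) and grouped into pulse events by 8-connected
    component labeling, and pulse durations are measured, pooled in blocks
    of 25 consecutive measurements, and compared between lateral and
    posterior cortical windows by one-way ANOVA with a bootstrap confidence
    interval on the posterior:lateral duration ratio.  A companion module
    quantifies posterior polarity crescents (e.g. Par-1) as a normalized
    intensity ratio versus arc distance from the posterior pole, using a
    follicle-cell band as internal reference.  A seeded synthetic-data
    generator emulates the imaging (stationary, intensity-oscillating foci
    with region-specific gamma-distributed durations; crescent images with
    a reference band) so that every stage is testable against known ground
    truth without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
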