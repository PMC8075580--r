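Package: sptkin
Title: Kinetic Modelling of Single-Particle Tracking Data and
    Fluctuation Analysis of Mutation Rates
Version: 0.1.0
Authors@R:
    person("Sussex", "Genomics Tools", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for live-cell single-particle tracking
    (sptPALM) of chromatin-associated protein complexes: localization
    quality filtering, frame-to-frame trajectory linking, lag-resolved
    jump-length distributions, and fitting of two- and three-state
    Brownian diffusion mixture models with localisation error and axial
    defocalisation correction, with model selection by AIC and
    extraction of the chromatin-bound fraction.  Includes a forward
    simulator of confined nuclear diffusion for validation, summary
    statistics for experimental repeats, and Luria-Delbruck fluctuation
    analysis of marker-loss rates with plating-efficiency correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
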