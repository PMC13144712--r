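Package: frogphen
Title: Mechanistic Simulation of Wood Frog Post-Hibernation Emergence Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples a simplified below-canopy microclimate model (diurnal
    downscaling of daily weather, canopy interception, degree-day snowmelt,
    one-dimensional soil heat conduction with snow insulation) to a rule-based
    model of wood frog (Rana sylvatica) emergence from hibernation.  Includes a
    synthetic daily-weather and pond-network generator, a climatological-normals
    null model, validation statistics against oviposition surveys, pooled
    decadal trend estimation with bootstrap confidence intervals, and
    one-at-a-time sensitivity analysis that attributes phenological variation
    to exogenous (meteorology, geography) versus endogenous (behavior,
    morphology, physiology) parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
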