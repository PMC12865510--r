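Package: ausr
Title: Fragment-Size Thresholds from Landscape-Scale Species Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to derive an objective, ecologically defined threshold
    separating "small" from "large" habitat fragments using only a
    fragment-by-species presence-absence matrix and fragment areas.
    Computes per-species landscape-scale incidence, the geometric-mean
    incidence of the species residing in each fragment (MSLIP), a
    resampling null model and standardised effect size (MSLIP_SES), and
    the area for unbiased species representation (A_USR) where the fitted
    MSLIP_SES - log(area) regression crosses zero.  Also provides power-law
    island species-area relationship fits with residual richness
    covariates, ranked species occupancy curve fits with a bimodality
    flag, a two-stage cross-landscape analysis of area slopes by
    generalised least squares with an exponential variance structure, and
    a synthetic fragmented-landscape generator with area-dependent
    species selection for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    emmeans,
    jsonlite,
    nlme,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
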