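Package: senflux
Title: Expression-Constrained Metabolic Flux Profiling of Cellular Senescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling pipeline for comparing
    proliferative and senescent cell states. Builds per-sample metabolic
    models by converting gene expression into Michaelis-Menten enzyme
    capacity bounds, computes flux profiles by flux variability analysis
    under ATP-maintenance and biomass constraints, identifies differential
    fluxes per study (case-control and passage time series), combines
    studies by fixed-effects meta-analysis, scores pathway-level shifts
    with a differential-abundance (DA) score and a bootstrap-without-
    replacement null, and ranks candidate intervention targets by
    all-against-all in-silico gene and metabolite knockouts summarised as
    effective scores with normal-background significance. Ships a
    synthetic-data generator with a toy network containing a planted
    mevalonate-like pathway for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    limma,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
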