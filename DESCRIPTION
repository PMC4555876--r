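Package: dasypop
Title: Random-Forest Dasymetric Population Mapping on Regular Grids
Version: 0.1.0
Authors@R:
    person("WorldPop-style", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Disaggregates administrative-unit census counts onto a fine
    regular grid using a population-density weighting layer predicted by a
    bagged regression-tree ensemble (random forest) fitted on zonal covariate
    aggregates, with iterative covariate elimination driven by out-of-bag
    permutation importance. Includes the raster primitives the pipeline needs
    (polygon rasterization by cell-centre containment, Euclidean distance
    transform, nearest-neighbour NoData filling, circular focal proportion,
    slope from a DEM), a simple areal-weighting baseline, temporal projection
    with urban/rural growth rates and national-total adjustment, a
    coarse-to-fine holdout validation with RMSE/%RMSE/MAE, a seeded synthetic
    landscape generator, and an end-to-end pipeline producing the full
    people-per-pixel / people-per-hectare product suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
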