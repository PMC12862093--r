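Package: SoilVegCoupling
Title: Soil Moisture-Vegetation Coupling Coordination Analysis for Raster Basins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of the coupling between volumetric soil
    moisture and vegetation condition over a river basin raster grid:
    layered soil-moisture inversion from screened field and spectral
    predictors (stepwise, ridge and partial least squares regression with
    rule-based model selection), construction of a composite vegetation
    index by principal component analysis with KMO and Bartlett screening,
    per-pixel Spearman rank-correlation significance mapping, the
    two-subsystem coupling coordination degree model with five-level
    classification, and Gini-impurity random-forest ranking of coupling
    drivers. A synthetic basin generator reproduces the statistical
    structure the analysis assumes (north-dry/south-wet gradient, seasonal
    cycles, linear soil-property truth, planted driver importance) so the
    whole pipeline runs and is tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), MASS, randomForest, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
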