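# SoilVegCoupling

Quantifying how vegetation condition and near-surface soil moisture
(SM) co-develop across a river-basin raster — for eco-hydrologists and
remote-sensing analysts studying semi-arid catchments, and for anyone
who needs a tested, reproducible implementation of the coupling
coordination workflow:

1. **Layered SM inversion.** Per depth layer (0–10, 10–20, 20–30 cm),
   candidate predictors (bulk density BD, capillary porosity P_cap,
   nutrients, band values) are screened by Pearson correlation
   (p < 0.05), sites are split 4:1, and three regressions — stepwise
   (partial-F entry/removal), closed-form ridge with CV penalty, and
   NIPALS PLSR with CV components — compete under the error gates
   RMSE < 0.05, MAE < 0.02, MAPE ≤ 20 %, with validation R² breaking
   the tie.
2. **Composite vegetation index.** Seven spectral indices (NDVI, EVI,
   SAVI, DVI, RVI, ARVI, GNDVI) are screened with KMO ≥ 0.5,
   Bartlett p < 0.05 and a 0.6 correlation gate against NPP and LAI;
   a correlation-matrix PCA with varimax rotation produces component
   score coefficients, which are combined by the components' shares of
   the rotated sums of squared loadings and normalized into the VEG
   weights.
3. **Per-pixel Spearman mapping.** ρ is Pearson on mid-ranks, with a
   two-sided p from t = ρ√((n−2)/(1−ρ²)) on n−2 df; pixels are classed
   significant-positive / significant-negative / non-significant at
   α = 0.05.
4. **Coupling coordination degree.** C = 2√(VEG·SM)/(VEG+SM),
   T = αVEG + βSM (α = β = 0.5), D = √(C·T), classified into five
   equal-width levels from Extreme Disorder (0, 0.2] to Highly
   Coordinated (0.8, 1.0].
5. **Driver ranking.** A Gini-impurity CART forest (Rcpp; 500 trees,
   mtry 2) on eight drivers — population density, elevation, slope,
   aspect, mean annual temperature/precipitation, land-surface
   temperature, potential evapotranspiration — with per-feature
   importance shares and Kendall-τ consistency across depths.

A synthetic basin generator (north-dry/south-wet gradient, July-peaked
seasonality, linear soil-property truth with known coefficients,
planted driver hierarchy) provides every input, so the full pipeline
runs offline and every stage is testable against planted truth.

Rasters travel as plain-text ESRI ASCII grids (`.asc`); sample tables
as CSV; configuration as YAML.

## Worked example

```r
library(SoilVegCoupling)

geom    <- generateGeometry(64, 64, cellSize = 20, seed = 1)
samples <- generateSoilSamples(170, smTruthConfig(noiseSd = 0.01),
                               geom, seed = 1)

screening <- screenPredictors(samples, depth = "0-10", alpha = 0.05)
head(screening, 4)
#>   predictor          r             p retained
#> 1     P_cap  0.9767409 2.833119e-114     TRUE
#> 2        VH  0.8739021  1.646552e-54     TRUE
#> 3        VV  0.8306755  1.380024e-44     TRUE
#> 4       B12 -0.7330200  6.383502e-30     TRUE

split <- splitSamples(samples, ratio = 4, seed = 1)   # 136/34 sites
model <- fitSMLR(subset(split$train, depth == "0-10"),
                 screening$predictor[screening$retained], depth = "0-10")
model
#> FittedModel [SMLR, depth 0-10]: SM = -0.119214 +0.0130763*P_cap +0.0907041*BD

evaluateModel(model, subset(split$valid, depth == "0-10"))
#>   method depth    R2   RMSE     MAE MAPE        p nValid
#> 1   SMLR  0-10 0.978 0.0109 0.00899 1.56 2.64e-31     34
```

Stepwise recovers the generator's truth structure (P_cap and BD, with
coefficients near the planted 0.013 and 0.084; the noise shifts them
slightly) and the validation errors sit inside all three selection
gates. The composite-index weights from the reference two-component
score equations:

```r
S <- matrix(c(0.570, 0.637, -0.367, -0.130, -0.245, 1.159), 3, 2,
            dimnames = list(c("NPP", "LAI", "ARVI"), NULL))
round(compositeWeights(S, rotatedSS = c(1.778, 1.083)), 3)
#>   NPP   LAI  ARVI
#> 0.373 0.370 0.257
```

Coupling arithmetic and driver ranking:

```r
c(C = couplingDegree(0.2, 0.8), T = harmonization(0.2, 0.8),
  D = couplingCoordination(0.8, 0.5))
#>         C         T         D
#> 0.8000000 0.5000000 0.6324555

drivers <- generateDriverStack(geom, seed = 1)   # LST, PET planted on top
imp <- driverImportance(drivers$drivers, drivers$latent,
                        nTrees = 200, seed = 1)
head(imp$importance[order(imp$importance$rank), ], 4)
#>  feature giniDecrease  share rank
#>      LST        55.70 0.4311    1
#>      PET        24.12 0.1867    2
#>      MAP        10.96 0.0848    3
#>    slope         8.43 0.0652    4
```

The two planted lead drivers come out on top. `runAll(pipelineConfig())`
chains every stage on a synthetic basin and writes rasters, tables and
a `summary.json`; `inst/cli/svcoupling` exposes the same stages as
shell subcommands (`simulate`, `composite`, `veg-index`, `invert`,
`correlate`, `couple`, `importance`, `run-all`).

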