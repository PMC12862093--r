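# Latent vegetation state used by the band generator: north-south
# gradient + smooth spatial texture + seasonal cycle peaking mid-year.
latentVegetation <- function(geom, month, gradientStrength = 1,
                             textureField = NULL) {
  s <- matrix(southness(geom), geom@nRows, geom@nCols)
  if (is.null(textureField))
    textureField <- smoothField(geom@nRows, geom@nCols,
                                range = max(8, geom@nRows / 8))
  seasonal <- exp(-((month - 7)^2) / 8)   # peaks in July
  clip01(0.18 + 0.32 * gradientStrength * s + 0.12 * textureField +
         0.30 * seasonal)
}

#' Synthetic band names
#' @return character vector of the ten generated bands.
#' @export
bandNames <- function() c("B2", "B3", "B4", "B6", "B8", "B8A", "B11",
                          "B12", "VH", "VV")

#' Generate a synthetic set of spectral and radar band rasters
#'
#' Produces the ten bands used by the pipeline for one month:
#' reflectance bands in [0, 1] and radar backscatter (VH, VV) in
#' decibels within [-30, 0]. All bands derive from a shared latent
#' vegetation/wetness state with (i) a north-south gradient such that
#' NDVI from B8/B4 is higher in the southern half, and (ii) a seasonal
#' cycle peaking at mid-year months.
#'
#' @param geom a [BasinGeometry-class].
#' @param month month index 1..12 controlling the seasonal state.
#' @param seed integer seed.
#' @param gradientStrength dimensionless gradient strength (default 1).
#' @return named list of [RasterGrid-class], one per [bandNames()].
#' @export
generateBandStack <- function(geom, month = 7, seed = NULL,
                              gradientStrength = 1) {
  stopifnot(is(geom, "BasinGeometry"), month >= 1, month <= 12)
  withSeed(if (is.null(seed)) NULL
           else childSeed(seed, "bands") + month, {
    nr <- geom@nRows; nc <- geom@nCols
    V <- latentVegetation(geom, month, gradientStrength)
    nz <- function(sd) matrix(rnorm(nr * nc, 0, sd), nr, nc)
    ndvi <- clip01(0.05 + 0.75 * V)
    B4 <- pmin(0.4, pmax(0.01, 0.03 + 0.16 * (1 - V) + nz(0.008)))
    B8 <- pmin(0.95, pmax(0.02, B4 * (1 + ndvi) / (1 - ndvi)))
    out <- list(
      B2  = clip01(0.8 * B4 + nz(0.005)),
      B3  = clip01(0.9 * B4 + 0.02 * V + nz(0.005)),
      B4  = B4,
      B6  = clip01(0.5 * B8 + 0.08 + nz(0.01)),
      B8  = B8,
      B8A = clip01(0.95 * B8 + nz(0.01)),
      B11 = clip01(0.32 - 0.18 * V + nz(0.012)),
      B12 = clip01(0.28 - 0.18 * V + nz(0.012)),
      VH  = pmin(0, pmax(-30, -25 + 10 * V + nz(0.8))),
      VV  = pmin(0, pmax(-30, -18 + 9 * V + nz(0.8))))
    lapply(out, rasterGrid, geom = geom)
  })
}

#' Generate a monthly time-series stack for one variable
#'
#' Convenience generator for monthly stacks of NDVI-like band-derived
#' variables or the gridded vegetation products NPP and LAI. All
#' variables share the latent seasonal/gradient state of
#' [generateBandStack()], plus observation noise, so vegetation
#' descriptors generated on the same seed are cross-correlated.
#'
#' @param geom a [BasinGeometry-class].
#' @param variable one of "NPP" (g C m-2 month-1), "LAI" (m2 m-2) or
#'   "VEGSTATE" (the unitless latent state itself).
#' @param years,months integer vectors defining the time axis.
#' @param seed integer seed.
#' @param noiseSd observation noise on the latent state scale.
#' @return a [TimeSeriesStack-class].
#' @export
generateProductSeries <- function(geom, variable = c("NPP", "LAI", "VEGSTATE"),
                                  years = 2017:2024, months = 1:12,
                                  seed = NULL, noiseSd = 0.03) {
  variable <- match.arg(variable)
  stopifnot(is(geom, "BasinGeometry"))
  withSeed(if (is.null(seed)) NULL else childSeed(seed, "series"), {
    nr <- geom@nRows; nc <- geom@nCols
    texture <- smoothField(nr, nc, range = max(8, nr / 8))
    tm <- expand.grid(month = months, year = years)[, c("year", "month")]
    layers <- vector("list", nrow(tm))
    for (i in seq_len(nrow(tm))) {
      V <- latentVegetation(geom, tm$month[i], textureField = texture)
      V <- clip01(V + matrix(rnorm(nr * nc, 0, noiseSd), nr, nc))
      v <- switch(variable,
                  NPP = 10 + 90 * V,
                  LAI = 0.2 + 4.3 * V,
                  VEGSTATE = V)
      v[!geom@mask] <- NA_real_
      layers[[i]] <- v
    }
    new("TimeSeriesStack", variable = variable, times = tm,
        layers = layers, geometry = geom)
  })
}

#' Generate coupled SM and VEG annual series with a planted spatial
#' correlation split
#'
#' Produces two aligned annual stacks sharing a common interannual
#' anomaly whose sign is positive in the southern half of the basin and
#' negative in the northern half: per-pixel Spearman correlation between
#' the two stacks should recover a south-positive / north-negative
#' class map.
#'
#' @param geom a [BasinGeometry-class].
#' @param nYears number of annual time steps (default 8).
#' @param startYear first year label.
#' @param seed integer seed.
#' @param anomalySd interannual anomaly scale; \code{noiseSd} is the
#'   independent pixel noise (small relative to the anomaly so the
#'   planted signs dominate).
#' @param noiseSd see above.
#' @return list with elements \code{sm} and \code{veg}
#'   ([TimeSeriesStack-class]) and \code{signGrid}, the planted +1/-1
#'   matrix.
#' @export
generateCoupledStacks <- function(geom, nYears = 8, startYear = 2017,
                                  seed = NULL, anomalySd = 0.1,
                                  noiseSd = 0.01) {
  stopifnot(is(geom, "BasinGeometry"), nYears >= 3)
  withSeed(if (is.null(seed)) NULL else childSeed(seed, "series") + 1L, {
    nr <- geom@nRows; nc <- geom@nCols
    s <- matrix(southness(geom), nr, nc)
    sgn <- ifelse(s > 0.5, 1, -1)
    smBase <- clip01(0.25 + 0.25 * s +
                     0.05 * smoothField(nr, nc, range = max(8, nr / 8)))
    vegBase <- clip01(0.3 + 0.3 * s +
                      0.05 * smoothField(nr, nc, range = max(8, nr / 8)))
    a <- rnorm(nYears, 0, anomalySd)
    mk <- function(base, signed) {
      layers <- lapply(seq_len(nYears), function(t) {
        v <- base + (if (signed) sgn else 1) * a[t] +
          matrix(rnorm(nr * nc, 0, noiseSd), nr, nc)
        v[!geom@mask] <- NA_real_
        v
      })
      layers
    }
    tm <- data.frame(year = startYear + seq_len(nYears) - 1L, month = 7L)
    sm <- new("TimeSeriesStack", variable = "SM", times = tm,
              layers = mk(smBase, FALSE), geometry = geom)
    veg <- new("TimeSeriesStack", variable = "VEG", times = tm,
               layers = mk(vegBase, TRUE), geometry = geom)
    sgn[!geom@mask] <- NA_real_
    list(sm = sm, veg = veg, signGrid = sgn)
  })
}
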