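#' Default generative truth for synthetic soil samples
#'
#' The generator draws soil physicochemistry per site and depth layer
#' and computes volumetric soil moisture from a linear equation per
#' depth plus Gaussian noise. The default coefficients are the package's
#' reference inversion equations for the three depth layers
#' (intercept, then named predictor coefficients), so
#' parameter-recovery tests double as fixtures of those equations:
#' \itemize{
#'   \item 0-10 cm:  SM = -0.105 + 0.013 P_cap + 0.084 BD
#'   \item 10-20 cm: SM = -0.123 + 0.012 P_cap + 0.101 BD + 0.002 TP +
#'     0.016 TK + 0.000004 B12 - 0.00001 B6
#'   \item 20-30 cm: SM = -0.115 + 0.013 P_cap + 0.091 BD
#' }
#'
#' @param noiseSd standard deviation of the additive moisture noise, in
#'   volumetric-fraction units (>= 0).
#' @param gradientStrength dimensionless strength of the north-dry /
#'   south-wet spatial gradient planted in the soil properties (0 = no
#'   gradient).
#' @param coefficients named list of per-depth coefficient vectors; each
#'   vector must contain an \code{intercept} element, remaining elements
#'   are named after sample-table columns.
#' @return a list of class \code{smTruthConfig}.
#' @export
smTruthConfig <- function(noiseSd = 0.01, gradientStrength = 1,
                          coefficients = NULL) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (is.null(coefficients))
    coefficients <- list(
      "0-10"  = c(intercept = -0.105, P_cap = 0.013, BD = 0.084),
      "10-20" = c(intercept = -0.123, P_cap = 0.012, BD = 0.101,
                  TP = 0.002, TK = 0.016, B12 = 0.000004, B6 = -0.00001),
      "20-30" = c(intercept = -0.115, P_cap = 0.013, BD = 0.091))
  stopifnot(all(vapply(coefficients,
                       function(cf) "intercept" %in% names(cf) &&
                         all(is.finite(cf)), logical(1))))
  structure(list(noiseSd = noiseSd, gradientStrength = gradientStrength,
                 coefficients = coefficients),
            class = "smTruthConfig")
}

#' Depth-layer labels of the sample table
#' @return character vector \code{c("0-10", "10-20", "20-30")} (cm).
#' @export
depthLayers <- function() c("0-10", "10-20", "20-30")

# Evaluate a truth equation on sample-table rows.
evalTruthEquation <- function(cf, data) {
  out <- rep(cf[["intercept"]], nrow(data))
  for (nm in setdiff(names(cf), "intercept")) {
    if (!nm %in% names(data))
      stop(sprintf("truth equation needs column '%s'", nm))
    out <- out + cf[[nm]] * data[[nm]]
  }
  out
}

#' Generate a synthetic soil-sample table
#'
#' Draws \code{nSites} sampling sites (three depth layers each) with
#' bulk density, porosities, nutrients, texture fractions and satellite
#' band values at the site, then computes soil moisture from the truth
#' equations plus Gaussian noise, clipped to [0, 1]. Capillary porosity
#' and bulk density carry a north-south gradient so the derived moisture
#' field is drier in the north, and the moisture-related bands (B12, B6,
#' VH, VV) co-vary with the porosity signal.
#'
#' Band columns are in scaled digital numbers (about 0-10000 for the
#' optical bands, decibels for VH/VV), matching the scale of the band
#' terms in the default truth equations; raster reflectances elsewhere
#' in the package are in [0, 1].
#'
#' @param nSites number of sampling sites (>= 20, default 170).
#' @param truth an [smTruthConfig()].
#' @param geom optional [BasinGeometry-class]; if supplied, site
#'   coordinates are drawn from inside-basin cells, otherwise from a
#'   unit square scaled to metres.
#' @param seed integer seed.
#' @return data.frame with one row per site x depth: \code{site, x, y,
#'   depth, BD, P_cap, P_non, TN, TP, TK, AK, clay, silt, sand, B2, B3,
#'   B4, B6, B8, B8A, B11, B12, VH, VV, SM}.
#' @examples
#' tab <- generateSoilSamples(30, smTruthConfig(noiseSd = 0), seed = 1)
#' nrow(tab)   # 90 = 30 sites x 3 depths
#' @export
generateSoilSamples <- function(nSites = 170, truth = smTruthConfig(),
                                geom = NULL, seed = NULL) {
  if (nSites < 20)
    stop("nSites must be >= 20 (enough for a 4:1 split and stepwise fitting)")
  stopifnot(inherits(truth, "smTruthConfig"))
  withSeed(if (is.null(seed)) NULL else childSeed(seed, "samples"), {
    if (is.null(geom)) {
      x <- runif(nSites) * 1000
      y <- runif(nSites) * 1000
      south <- 1 - y / 1000
    } else {
      cells <- which(geom@mask)
      pick <- sample(cells, nSites, replace = nSites > length(cells))
      ri <- (pick - 1L) %% geom@nRows + 1L
      ci <- (pick - 1L) %/% geom@nRows + 1L
      cc <- cellCenters(geom)
      x <- cc$x[ci]; y <- cc$y[ri]
      south <- (ri - 0.5) / geom@nRows
    }
    gs <- truth$gradientStrength
    # site-level latent wetness: southern sites more porous, less dense
    uP <- clip01(0.5 + 0.35 * gs * (2 * south - 1) + rnorm(nSites, 0, 0.18))
    uB <- clip01(0.5 - 0.30 * gs * (2 * south - 1) + rnorm(nSites, 0, 0.20))
    rows <- vector("list", 3L)
    for (d in 1:3) {
      # mild depth drift and within-site variation
      uPd <- clip01(uP - 0.03 * (d - 1) + rnorm(nSites, 0, 0.05))
      uBd <- clip01(uB + 0.04 * (d - 1) + rnorm(nSites, 0, 0.05))
      tab <- data.frame(
        site = seq_len(nSites), x = x, y = y,
        depth = depthLayers()[d],
        BD = 0.9 + 0.7 * uBd,
        P_cap = 30 + 30 * uPd,
        P_non = runif(nSites, 2, 12),
        TN = runif(nSites, 0.5, 2.5),
        TP = runif(nSites, 0.4, 1.2),
        TK = runif(nSites, 5, 14),
        AK = runif(nSites, 50, 200))
      tex <- matrix(stats::rgamma(3 * nSites, shape = c(2, 5, 4)), ncol = 3,
                    byrow = TRUE)
      tex <- 100 * tex / rowSums(tex)
      tab$clay <- tex[, 1]; tab$silt <- tex[, 2]; tab$sand <- tex[, 3]
      # bands at site (digital numbers); moisture-related bands track uPd
      tab$B2 <- pmax(100, 900 + rnorm(nSites, 0, 150))
      tab$B3 <- pmax(100, 1100 + rnorm(nSites, 0, 150))
      tab$B4 <- pmax(100, 1300 - 300 * uPd + rnorm(nSites, 0, 150))
      tab$B6 <- pmax(200, 2200 + 500 * uPd + rnorm(nSites, 0, 200))
      tab$B8 <- pmax(200, 2500 + 800 * uPd + rnorm(nSites, 0, 250))
      tab$B8A <- pmax(200, 0.95 * tab$B8 + rnorm(nSites, 0, 100))
      tab$B11 <- pmax(200, 2600 - 900 * uPd + rnorm(nSites, 0, 250))
      tab$B12 <- pmax(200, 2400 - 1100 * uPd + rnorm(nSites, 0, 250))
      tab$VH <- pmin(0, pmax(-30, -24 + 9 * uPd + rnorm(nSites, 0, 1.2)))
      tab$VV <- pmin(0, pmax(-30, -17 + 8 * uPd + rnorm(nSites, 0, 1.2)))
      sm <- evalTruthEquation(truth$coefficients[[depthLayers()[d]]], tab)
      if (truth$noiseSd > 0) sm <- sm + rnorm(nSites, 0, truth$noiseSd)
      tab$SM <- clip01(sm)
      rows[[d]] <- tab
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$site, match(out$depth, depthLayers())), ]
    rownames(out) <- NULL
    out
  })
}
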