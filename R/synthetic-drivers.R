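#' Names of the eight coupling drivers
#'
#' Anthropogenic (population density), topographic (elevation, slope,
#' aspect) and climatic (mean annual temperature, mean annual
#' precipitation, land-surface temperature, potential
#' evapotranspiration) factors.
#'
#' @return character vector of length 8.
#' @export
driverNames <- function() c("popDensity", "elevation", "slope", "aspect",
                            "MAT", "MAP", "LST", "PET")

#' Generate driver rasters with a planted importance ordering
#'
#' Draws eight mutually independent smooth random fields, scales each to
#' a plausible physical range, and builds a latent coordination field as
#' a logistic function of the standardized drivers with weights
#' decreasing geometrically along \code{plantedOrder}. Because the
#' drivers are independent and the latent field is a known monotone
#' function of them, importance-recovery is testable: a Gini forest fit
#' on (drivers, discretized latent field) should rank the first planted
#' drivers on top.
#'
#' @param geom a [BasinGeometry-class].
#' @param plantedOrder permutation of [driverNames()], most important
#'   first. The default puts land-surface temperature and potential
#'   evapotranspiration first and the terrain-shape factors last,
#'   matching the generator's reference driver hierarchy.
#' @param decay geometric weight decay along the order (0 < decay <= 1;
#'   1 = all-equal weights).
#' @param weights optional explicit positive weights in
#'   \code{plantedOrder} order (normalized internally); overrides
#'   \code{decay}.
#' @param seed integer seed.
#' @return list with \code{drivers} (named list of
#'   [RasterGrid-class]), \code{latent} (the coordination field in
#'   (0, 1)), \code{weights} (named, ordered as [driverNames()]) and
#'   \code{order}.
#' @export
generateDriverStack <- function(geom,
                                plantedOrder = c("LST", "PET", "MAP", "MAT",
                                                 "elevation", "popDensity",
                                                 "slope", "aspect"),
                                decay = 0.5, seed = NULL,
                                weights = NULL) {
  stopifnot(is(geom, "BasinGeometry"))
  if (!setequal(plantedOrder, driverNames()) ||
      length(plantedOrder) != 8L)
    stop("plantedOrder must be a permutation of driverNames()")
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]")
  if (!is.null(weights) && (length(weights) != 8L || any(weights <= 0)))
    stop("weights must be 8 positive values in plantedOrder order")
  withSeed(if (is.null(seed)) NULL else childSeed(seed, "drivers"), {
    nr <- geom@nRows; nc <- geom@nCols
    f <- function() smoothField(nr, nc, range = max(6, nr / 10))
    raw <- list(
      popDensity = exp(2 + 1.2 * f()),            # persons km-2
      elevation  = 1500 + 400 * f(),              # m
      slope      = pmin(45, pmax(0, 12 + 7 * f())),  # deg
      aspect     = (180 + 80 * f()) %% 360,       # deg
      MAT        = 7 + 1.5 * f(),                 # deg C
      MAP        = 380 + 60 * f(),                # mm
      LST        = 295 + 4 * f(),                 # K
      PET        = 800 + 120 * f())               # mm
    w <- if (is.null(weights)) decay^(seq_len(8L) - 1L) else weights
    w <- w / sum(w)
    names(w) <- plantedOrder
    w <- w[driverNames()]
    z <- 0
    for (nm in driverNames()) {
      v <- raw[[nm]][geom@mask]
      zs <- (raw[[nm]] - mean(v)) / sd(v)
      z <- z + w[[nm]] * zs
    }
    latent <- 1 / (1 + exp(-4 * z))   # spreads classes across the bins
    list(drivers = lapply(raw, rasterGrid, geom = geom),
         latent = rasterGrid(latent, geom),
         weights = w, order = plantedOrder)
  })
}
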