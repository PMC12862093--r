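#' @import methods
#' @importFrom stats cor pf pt pchisq qnorm rnorm runif sd var lm coef anova
#'   add1 drop1 quantile aggregate complete.cases varimax approx predict
#'   p.adjust kmeans
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib SoilVegCoupling, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' BasinGeometry: shared raster geometry of a study basin
#'
#' Every raster produced or consumed by the package carries a
#' \code{BasinGeometry}: grid dimensions, cell size, map origin and the
#' basin mask. Rasters are only combined when their geometries are
#' identical; a mismatch raises an error before any computation.
#'
#' Row 1 is the northern (top) edge of the grid, matching the on-disk
#' row order of ASCII grid rasters. The origin is the map coordinate of
#' the lower-left corner.
#'
#' @slot nRows,nCols integer grid dimensions (both >= 8).
#' @slot cellSize numeric, cell edge length in metres.
#' @slot origin numeric length-2, (x, y) of the lower-left corner.
#' @slot mask logical matrix (nRows x nCols); TRUE marks cells inside the
#'   basin, FALSE marks outside-basin (nodata) cells.
#' @exportClass BasinGeometry
setClass("BasinGeometry",
  representation(nRows = "integer", nCols = "integer", cellSize = "numeric",
                 origin = "numeric", mask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@nRows) != 1L || length(object@nCols) != 1L ||
        object@nRows < 8L || object@nCols < 8L)
      msg <- c(msg, "grid dimensions must be single integers >= 8")
    if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a positive number")
    if (length(object@origin) != 2L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be finite (x, y)")
    if (!is.logical(object@mask) ||
        !identical(dim(object@mask), c(object@nRows, object@nCols)))
      msg <- c(msg, "mask must be a logical nRows x nCols matrix")
    else if (!any(object@mask))
      msg <- c(msg, "mask must contain at least one inside-basin cell")
    if (length(msg)) msg else TRUE
  })

#' RasterGrid: a single-band float raster on a basin geometry
#'
#' Values are stored as a numeric matrix; \code{NA} is the in-memory
#' nodata value and is forced wherever the geometry mask is FALSE.
#'
#' @slot values numeric matrix (nRows x nCols), NA = nodata.
#' @slot geometry a [BasinGeometry-class].
#' @seealso [rasterGrid()], [readAsciiGrid()], [writeAsciiGrid()]
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(values = "matrix", geometry = "BasinGeometry"),
  validity = function(object) {
    g <- object@geometry
    if (!is.numeric(object@values))
      return("values must be numeric")
    if (!identical(dim(object@values), c(g@nRows, g@nCols)))
      return("values dimensions must match geometry")
    if (any(!is.na(object@values[!g@mask])))
      return("cells outside the basin mask must be NA")
    TRUE
  })

#' TimeSeriesStack: an ordered monthly raster time series
#'
#' @slot variable character, the variable name (e.g. "NDVI", "SM").
#' @slot times data.frame with integer columns \code{year} and
#'   \code{month}; rows strictly increasing in time.
#' @slot layers list of numeric value matrices, one per time step, all on
#'   the shared geometry.
#' @slot geometry a [BasinGeometry-class].
#' @exportClass TimeSeriesStack
setClass("TimeSeriesStack",
  representation(variable = "character", times = "data.frame",
                 layers = "list", geometry = "BasinGeometry"),
  validity = function(object) {
    tm <- object@times
    if (!all(c("year", "month") %in% names(tm)))
      return("times must have year and month columns")
    if (nrow(tm) != length(object@layers))
      return("one layer per time step required")
    key <- tm$year * 12L + tm$month
    if (nrow(tm) > 1L && any(diff(key) <= 0))
      return("time steps must be strictly increasing")
    if (any(tm$month < 1L | tm$month > 12L))
      return("month must be in 1..12")
    g <- object@geometry
    ok <- vapply(object@layers, function(m)
      identical(dim(m), c(g@nRows, g@nCols)), logical(1))
    if (!all(ok)) return("all layers must match the geometry dimensions")
    TRUE
  })

#' PcaResult: correlation-matrix PCA with rotation, in the layout used
#' for composite-indicator construction
#'
#' Holds the eigen decomposition of the indicator correlation matrix,
#' the retained (and varimax-rotated) loadings, the component score
#' coefficient matrix and the communalities, i.e. everything needed to
#' combine components into composite-index weights.
#'
#' @slot eigenvalues numeric, descending; sums to the number of
#'   indicators.
#' @slot variancePct,cumulativePct per-component percentage of variance
#'   and its running sum (ends at 100).
#' @slot loadings unrotated loading matrix (indicator x component),
#'   eigenvector times sqrt(eigenvalue).
#' @slot rotatedLoadings varimax-rotated loadings of the retained
#'   components.
#' @slot rotatedSS rotated sums of squared loadings (one per retained
#'   component).
#' @slot scoreCoefficients component score coefficient matrix,
#'   solve(R) \%*\% rotatedLoadings.
#' @slot communalities per-indicator variance explained by the retained
#'   components.
#' @slot nRetained integer, number of retained components.
#' @exportClass PcaResult
setClass("PcaResult",
  representation(eigenvalues = "numeric", variancePct = "numeric",
                 cumulativePct = "numeric", loadings = "matrix",
                 rotatedLoadings = "matrix", rotatedSS = "numeric",
                 scoreCoefficients = "matrix", communalities = "numeric",
                 nRetained = "integer"),
  validity = function(object) {
    p <- length(object@eigenvalues)
    if (abs(sum(object@eigenvalues) - p) > 1e-6)
      return("eigenvalues of a correlation matrix must sum to p")
    if (any(diff(object@cumulativePct) < -1e-9))
      return("cumulative percentage must be non-decreasing")
    if (abs(object@cumulativePct[p] - 100) > 1e-6)
      return("cumulative percentage must end at 100")
    if (any(object@communalities < -1e-9 | object@communalities > 1 + 1e-9))
      return("communalities must lie in [0, 1]")
    if (object@nRetained < 1L || object@nRetained > p)
      return("nRetained out of range")
    TRUE
  })

#' FittedModel: a fitted soil-moisture regression for one depth layer
#'
#' @slot method "SMLR", "Ridge" or "PLSR".
#' @slot depth depth-layer label, e.g. "0-10".
#' @slot intercept numeric intercept.
#' @slot coefficients named numeric vector on the original predictor
#'   scale.
#' @slot hyper list of method hyperparameters (ridge penalty, PLSR
#'   component count, stepwise thresholds).
#' @slot screened character, the predictor pool the model was allowed to
#'   draw from; retained predictors are always a subset.
#' @exportClass FittedModel
setClass("FittedModel",
  representation(method = "character", depth = "character",
                 intercept = "numeric", coefficients = "numeric",
                 hyper = "list", screened = "character"),
  validity = function(object) {
    if (!object@method %in% c("SMLR", "Ridge", "PLSR"))
      return("method must be SMLR, Ridge or PLSR")
    if (!all(is.finite(object@intercept)) ||
        !all(is.finite(object@coefficients)))
      return("coefficients must be finite")
    if (length(object@coefficients) &&
        is.null(names(object@coefficients)))
      return("coefficients must be named")
    if (length(object@coefficients) &&
        !all(names(object@coefficients) %in% object@screened))
      return("retained predictors must be a subset of the screened pool")
    TRUE
  })

#' CorrelationMaps: per-pixel Spearman correlation and significance
#'
#' @slot rho,p,n numeric matrices of the rank correlation, its two-sided
#'   p-value and the series length per pixel.
#' @slot classGrid integer matrix: 1 = significant positive, 2 =
#'   significant negative, 3 = not significant, NA = nodata.
#' @slot alpha numeric significance level used for classification.
#' @slot geometry a [BasinGeometry-class].
#' @exportClass CorrelationMaps
setClass("CorrelationMaps",
  representation(rho = "matrix", p = "matrix", n = "matrix",
                 classGrid = "matrix", alpha = "numeric",
                 geometry = "BasinGeometry"),
  validity = function(object) {
    r <- object@rho
    if (any(abs(r) > 1 + 1e-9, na.rm = TRUE)) return("|rho| must be <= 1")
    pv <- object@p
    if (any(pv < -1e-12 | pv > 1 + 1e-12, na.rm = TRUE))
      return("p-values must lie in [0, 1]")
    if (!all(object@classGrid %in% c(1L, 2L, 3L, NA), TRUE))
      return("classGrid codes must be 1, 2, 3 or NA")
    TRUE
  })

#' CouplingMaps: coupling degree, harmonization, coordination and class
#'
#' @slot cGrid,tGrid,dGrid numeric matrices: coupling degree,
#'   harmonization index and coupling coordination degree, each in
#'   [0, 1] where defined.
#' @slot classGrid integer matrix of ordinal classes 1..5 (see
#'   [ccdLevels()]), NA = nodata.
#' @slot alpha,beta subsystem weights of the harmonization index
#'   (alpha + beta = 1).
#' @slot form "sqrt" (geometric-mean coupling, the default model) or
#'   "harmonic" (harmonic-mean sensitivity variant).
#' @slot geometry a [BasinGeometry-class].
#' @exportClass CouplingMaps
setClass("CouplingMaps",
  representation(cGrid = "matrix", tGrid = "matrix", dGrid = "matrix",
                 classGrid = "matrix", alpha = "numeric", beta = "numeric",
                 form = "character", geometry = "BasinGeometry"),
  validity = function(object) {
    if (abs(object@alpha + object@beta - 1) > 1e-9)
      return("alpha + beta must equal 1")
    for (nm in c("cGrid", "tGrid", "dGrid")) {
      v <- slot(object, nm)
      if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
        return(sprintf("%s must lie in [0, 1]", nm))
    }
    if (!all(object@classGrid %in% c(1:5, NA), TRUE))
      return("classGrid codes must be 1..5 or NA")
    TRUE
  })
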