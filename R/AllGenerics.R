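#' Accessors for basin rasters and stacks
#'
#' \code{geometry} returns the shared [BasinGeometry-class];
#' \code{gridValues} the numeric value matrix (NA = nodata);
#' \code{basinMask} the logical inside-basin mask; \code{nLayers} the
#' number of time steps of a stack.
#'
#' @param x a package object carrying a geometry.
#' @return see Description.
#' @aliases geometry gridValues basinMask nLayers
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname accessors
#' @export
setGeneric("basinMask", function(x) standardGeneric("basinMask"))

#' @rdname accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname accessors
setMethod("geometry", "BasinGeometry", function(x) x)
#' @rdname accessors
setMethod("geometry", "RasterGrid", function(x) x@geometry)
#' @rdname accessors
setMethod("geometry", "TimeSeriesStack", function(x) x@geometry)
#' @rdname accessors
setMethod("geometry", "CorrelationMaps", function(x) x@geometry)
#' @rdname accessors
setMethod("geometry", "CouplingMaps", function(x) x@geometry)

#' @rdname accessors
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname accessors
setMethod("basinMask", "BasinGeometry", function(x) x@mask)
#' @rdname accessors
setMethod("basinMask", "RasterGrid", function(x) x@geometry@mask)
#' @rdname accessors
setMethod("basinMask", "TimeSeriesStack", function(x) x@geometry@mask)

#' @rdname accessors
setMethod("nLayers", "TimeSeriesStack", function(x) length(x@layers))

setMethod("dim", "BasinGeometry", function(x) c(x@nRows, x@nCols))
setMethod("dim", "RasterGrid", function(x) dim(x@geometry))

setMethod("show", "BasinGeometry", function(object) {
  cat(sprintf("BasinGeometry: %d x %d cells, %.6g m cells, %.1f%% inside basin\n",
              object@nRows, object@nCols, object@cellSize,
              100 * mean(object@mask)))
})

setMethod("show", "RasterGrid", function(object) {
  v <- object@values[basinMask(object)]
  cat(sprintf("RasterGrid %d x %d; basin cells: %d; range [%.4g, %.4g]\n",
              nrow(object@values), ncol(object@values), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

setMethod("show", "TimeSeriesStack", function(object) {
  tm <- object@times
  cat(sprintf("TimeSeriesStack '%s': %d layers (%d-%02d .. %d-%02d), %d x %d\n",
              object@variable, nrow(tm), tm$year[1], tm$month[1],
              tm$year[nrow(tm)], tm$month[nrow(tm)],
              object@geometry@nRows, object@geometry@nCols))
})

setMethod("show", "PcaResult", function(object) {
  cat(sprintf("PcaResult: %d indicators, %d retained component(s)\n",
              length(object@eigenvalues), object@nRetained))
  cat("eigenvalues:", paste(sprintf("%.3f", object@eigenvalues),
                            collapse = ", "), "\n")
  cat("cumulative %:", paste(sprintf("%.3f", object@cumulativePct),
                             collapse = ", "), "\n")
})

setMethod("show", "FittedModel", function(object) {
  terms <- paste(sprintf("%+.6g*%s", object@coefficients,
                         names(object@coefficients)), collapse = " ")
  cat(sprintf("FittedModel [%s, depth %s]: SM = %.6g %s\n",
              object@method, object@depth, object@intercept, terms))
})

setMethod("show", "CorrelationMaps", function(object) {
  fr <- areaProportions(object)
  cat(sprintf(
    "CorrelationMaps (alpha = %.3g): sig+ %.1f%%, sig- %.1f%%, ns %.1f%%\n",
    object@alpha, 100 * fr["sig_pos"], 100 * fr["sig_neg"],
    100 * fr["nonsig"]))
})

setMethod("show", "CouplingMaps", function(object) {
  d <- object@dGrid[basinMask(geometry(object))]
  cat(sprintf("CouplingMaps (%s form, alpha = %.2f): mean D = %.3f\n",
              object@form, object@alpha, mean(d, na.rm = TRUE)))
})
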