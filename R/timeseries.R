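#' Construct a TimeSeriesStack
#'
#' @param layers list of [RasterGrid-class] or numeric value matrices,
#'   one per time step, in time order.
#' @param years,months integer vectors (recycled against each other)
#'   labelling the time steps.
#' @param variable variable name.
#' @param geom geometry; taken from the first RasterGrid layer when
#'   omitted.
#' @return a [TimeSeriesStack-class].
#' @export
timeSeriesStack <- function(layers, years, months, variable = "var",
                            geom = NULL) {
  n <- length(layers)
  tm <- data.frame(year = as.integer(rep_len(years, n)),
                   month = as.integer(rep_len(months, n)))
  if (is.null(geom)) {
    if (!is(layers[[1]], "RasterGrid"))
      stop("geom required when layers are plain matrices")
    geom <- geometry(layers[[1]])
  }
  mats <- lapply(layers, function(l) {
    if (is(l, "RasterGrid")) { assertSameGeometry(l, geom); gridValues(l) }
    else { l[!geom@mask] <- NA_real_; l }
  })
  new("TimeSeriesStack", variable = variable, times = tm, layers = mats,
      geometry = geom)
}

stackArray <- function(stack) {
  arr <- array(unlist(stack@layers, use.names = FALSE),
               dim = c(stack@geometry@nRows, stack@geometry@nCols,
                       length(stack@layers)))
  arr
}

stackFromArray <- function(stack, arr) {
  layers <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  new("TimeSeriesStack", variable = stack@variable, times = stack@times,
      layers = layers, geometry = stack@geometry)
}

stackIndex <- function(stack, year, month) {
  i <- which(stack@times$year == year & stack@times$month == month)
  if (length(i) != 1L) NA_integer_ else i
}

#' Flag temporal outliers in a raster time series
#'
#' A cell-time observation is flagged when (i) its value falls below
#' \code{lowThreshold} (radiometric floor, e.g. cloud shadow or snow in
#' an index expected to be positive), or (ii) it deviates from the mean
#' of its two temporal neighbours by more than \code{spikeFactor} times
#' the absolute difference of those neighbours (spectral spike). The
#' first and last time steps are only subject to the floor rule.
#'
#' @param stack a [TimeSeriesStack-class] with at least 3 layers.
#' @param lowThreshold radiometric floor (same units as the variable).
#' @param spikeFactor spike sensitivity; smaller flags more.
#' @return logical array (rows x cols x time); TRUE = flagged. Nodata
#'   cells are never flagged.
#' @export
flagOutliers <- function(stack, lowThreshold = 0, spikeFactor = 2) {
  if (nLayers(stack) < 3L) stop("stack must have at least 3 time steps")
  arr <- stackArray(stack)
  nt <- dim(arr)[3]
  flags <- !is.na(arr) & arr < lowThreshold
  prev <- arr[, , seq_len(nt - 2L), drop = FALSE]
  nxt <- arr[, , seq_len(nt - 2L) + 2L, drop = FALSE]
  mid <- arr[, , seq_len(nt - 2L) + 1L, drop = FALSE]
  nbMean <- (prev + nxt) / 2
  nbRange <- abs(nxt - prev)
  spike <- !is.na(mid) & !is.na(nbMean) &
    abs(mid - nbMean) > spikeFactor * nbRange
  flags[, , seq_len(nt - 2L) + 1L] <-
    flags[, , seq_len(nt - 2L) + 1L, drop = FALSE] | spike
  flags
}

#' Linearly gap-fill flagged observations
#'
#' Flagged cell-times are replaced by linear interpolation in time
#' between the nearest unflagged neighbours; gaps at the series
#' boundaries are filled by nearest-value extension. Unflagged cells
#' are never altered. A cell with fewer than two unflagged time points
#' becomes nodata for the whole series (counted in a message).
#'
#' @param stack a [TimeSeriesStack-class].
#' @param flags logical array from [flagOutliers()].
#' @return a gap-filled [TimeSeriesStack-class].
#' @export
linearGapfill <- function(stack, flags) {
  arr <- stackArray(stack)
  stopifnot(identical(dim(arr), dim(flags)))
  nt <- dim(arr)[3]
  tIdx <- seq_len(nt)
  dropped <- 0L
  mask <- stack@geometry@mask
  for (i in seq_len(dim(arr)[1])) for (j in seq_len(dim(arr)[2])) {
    if (!mask[i, j]) next
    f <- flags[i, j, ]
    if (!any(f)) next
    y <- arr[i, j, ]
    valid <- !f & !is.na(y)
    if (sum(valid) < 2L) {
      arr[i, j, ] <- NA_real_
      dropped <- dropped + 1L
      next
    }
    fill <- approx(tIdx[valid], y[valid], xout = tIdx[f], rule = 2)$y
    arr[i, j, f] <- fill
  }
  if (dropped > 0L)
    message(sprintf("linearGapfill: %d cell(s) with < 2 valid points set to nodata",
                    dropped))
  stackFromArray(stack, arr)
}

#' Maximum-value composite over a temporal window
#'
#' Cellwise maximum of the valid (non-nodata) observations in the
#' selected layers; cells with no valid observation become nodata.
#'
#' @param stack a [TimeSeriesStack-class].
#' @param layers integer indices of the layers forming the window
#'   (default: all).
#' @return a [RasterGrid-class].
#' @export
mvcComposite <- function(stack, layers = seq_len(nLayers(stack))) {
  if (length(layers) < 1L) stop("empty compositing window")
  arr <- stackArray(stack)[, , layers, drop = FALSE]
  out <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  rasterGrid(out, stack@geometry)
}

seasonMonths <- list(spring = 3:5, summer = 6:8, autumn = 9:11,
                     winter = c(12L, 1L, 2L))

#' Seasonal and annual aggregation of a monthly stack
#'
#' \code{seasonalAggregate} returns the cellwise mean over a season's
#' months (spring: Mar-May, summer: Jun-Aug, autumn: Sep-Nov; winter of
#' year y spans Dec of y-1 plus Jan and Feb of y). \code{annualMean}
#' averages all 12 months of a year. Missing months raise an error
#' naming them.
#'
#' @param stack a monthly [TimeSeriesStack-class].
#' @param year the year being aggregated (for winter, the
#'   January/February year).
#' @param season one of "spring", "summer", "autumn", "winter".
#' @return a [RasterGrid-class].
#' @export
seasonalAggregate <- function(stack, year,
                              season = c("spring", "summer", "autumn",
                                         "winter")) {
  season <- match.arg(season)
  mo <- seasonMonths[[season]]
  yr <- rep(year, length(mo))
  if (season == "winter") yr[mo == 12L] <- year - 1L
  idx <- mapply(stackIndex, year = yr, month = mo,
                MoreArgs = list(stack = stack))
  if (any(is.na(idx)))
    stop(sprintf("missing month(s) for %s %d: %s", season, year,
                 paste(sprintf("%d-%02d", yr[is.na(idx)], mo[is.na(idx)]),
                       collapse = ", ")))
  arr <- stackArray(stack)[, , idx, drop = FALSE]
  rasterGrid(apply(arr, c(1, 2), mean), stack@geometry)
}

#' @rdname seasonalAggregate
#' @export
annualMean <- function(stack, year) {
  idx <- vapply(1:12, function(m) stackIndex(stack, year, m), integer(1))
  if (any(is.na(idx)))
    stop(sprintf("missing month(s) for year %d: %s", year,
                 paste((1:12)[is.na(idx)], collapse = ", ")))
  arr <- stackArray(stack)[, , idx, drop = FALSE]
  rasterGrid(apply(arr, c(1, 2), mean), stack@geometry)
}
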