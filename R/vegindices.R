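# Core cellwise index arithmetic shared by the RasterGrid and numeric
# methods. Zero denominators become NA (nodata) so downstream
# statistics stay finite; NA inputs propagate.
indexFormula <- function(index, nir, red = NULL, blue = NULL, green = NULL) {
  safeDiv <- function(num, den) {
    out <- num / den
    out[!is.na(den) & den == 0] <- NA_real_
    out
  }
  switch(index,
    ndvi  = safeDiv(nir - red, nir + red),
    evi   = safeDiv(2.5 * (nir - red), nir + 6 * red - 7.5 * blue + 1),
    savi  = safeDiv(1.5 * (nir - red), nir + red + 0.5),
    dvi   = nir - red,
    rvi   = safeDiv(nir, red),
    arvi  = {
      rb <- 2 * red - blue
      safeDiv(nir - rb, nir + rb)
    },
    gndvi = safeDiv(nir - green, nir + green),
    stop(sprintf("unknown index '%s'", index)))
}

indexBands <- list(ndvi = c("nir", "red"), evi = c("nir", "red", "blue"),
                   savi = c("nir", "red"), dvi = c("nir", "red"),
                   rvi = c("nir", "red"), arvi = c("nir", "red", "blue"),
                   gndvi = c("nir", "green"))

#' Vegetation indices from reflectance bands
#'
#' Cellwise spectral vegetation indices. Bands correspond to the
#' Sentinel-2 convention used throughout the package: NIR = B8,
#' Red = B4, Blue = B2, Green = B3, all reflectances in [0, 1].
#' \describe{
#'   \item{NDVI}{(NIR - Red) / (NIR + Red)}
#'   \item{EVI}{2.5 (NIR - Red) / (NIR + 6 Red - 7.5 Blue + 1)}
#'   \item{SAVI}{1.5 (NIR - Red) / (NIR + Red + 0.5), soil factor
#'     L = 0.5}
#'   \item{DVI}{NIR - Red}
#'   \item{RVI}{NIR / Red}
#'   \item{ARVI}{(NIR - (2 Red - Blue)) / (NIR + (2 Red - Blue)),
#'     the atmospherically resistant form}
#'   \item{GNDVI}{(NIR - Green) / (NIR + Green)}
#' }
#' Cells with a zero denominator (and cells that are nodata in any used
#' band) become nodata.
#'
#' @param index one of "ndvi", "evi", "savi", "dvi", "rvi", "arvi",
#'   "gndvi".
#' @param nir,red,blue,green [RasterGrid-class] objects on a shared
#'   geometry, or plain numeric vectors/matrices. Only the bands the
#'   chosen index uses are required.
#' @return a [RasterGrid-class] (or numeric, matching the input type).
#' @examples
#' vegIndex("ndvi", nir = 0.5, red = 0.1)   # 0.6667
#' @export
vegIndex <- function(index, nir, red = NULL, blue = NULL, green = NULL) {
  index <- match.arg(tolower(index), names(indexBands))
  need <- indexBands[[index]]
  args <- list(nir = nir, red = red, blue = blue, green = green)
  miss <- need[vapply(args[need], is.null, logical(1))]
  if (length(miss))
    stop(sprintf("index '%s' requires band(s): %s", index,
                 paste(miss, collapse = ", ")))
  grids <- vapply(args[need], function(a) is(a, "RasterGrid"), logical(1))
  if (any(grids)) {
    if (!all(grids)) stop("mix of RasterGrid and numeric band inputs")
    ref <- args[[need[1]]]
    for (nm in need[-1]) assertSameGeometry(ref, args[[nm]])
    vals <- lapply(args[need], gridValues)
    if (all(is.na(vals[[1]][basinMask(ref)])))
      stop("all-nodata band input")
    out <- do.call(indexFormula,
                   c(list(index = index), stats::setNames(vals, need)))
    rasterGrid(out, geometry(ref))
  } else {
    do.call(indexFormula, c(list(index = index), args[need]))
  }
}

#' @rdname vegIndex
#' @export
ndvi <- function(nir, red) vegIndex("ndvi", nir = nir, red = red)

#' @rdname vegIndex
#' @export
evi <- function(nir, red, blue) vegIndex("evi", nir = nir, red = red,
                                         blue = blue)

#' @rdname vegIndex
#' @export
savi <- function(nir, red) vegIndex("savi", nir = nir, red = red)

#' @rdname vegIndex
#' @export
dvi <- function(nir, red) vegIndex("dvi", nir = nir, red = red)

#' @rdname vegIndex
#' @export
rvi <- function(nir, red) vegIndex("rvi", nir = nir, red = red)

#' @rdname vegIndex
#' @export
arvi <- function(nir, red, blue) vegIndex("arvi", nir = nir, red = red,
                                          blue = blue)

#' @rdname vegIndex
#' @export
gndvi <- function(nir, green) vegIndex("gndvi", nir = nir, green = green)
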