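# shared input check for subsystem scores
checkUnit <- function(v, nm) {
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop(sprintf("%s values must lie in [0, 1]", nm))
}

asValues <- function(x) if (is(x, "RasterGrid")) gridValues(x) else x

wrapLike <- function(values, template) {
  if (is(template, "RasterGrid")) rasterGrid(values, geometry(template))
  else values
}

#' Coupling degree of the vegetation and soil-moisture subsystems
#'
#' The coupling degree C measures the balance of the two subsystem
#' scores. The default geometric-mean form is
#' C = 2 sqrt(VEG x SM) / (VEG + SM), which equals 1 exactly when the
#' two scores are equal and positive and 0 when either subsystem score
#' is 0. When both scores are 0 the ratio is 0/0 and the cell becomes
#' nodata (coupling of two absent subsystems is undefined). The
#' \code{"harmonic"} form 2 VEG SM / (VEG + SM) is provided for
#' sensitivity analysis.
#'
#' @param veg,sm subsystem scores in [0, 1]: [RasterGrid-class] objects
#'   on a shared geometry, or plain numerics.
#' @param form "sqrt" (default) or "harmonic".
#' @return coupling degree, same container type as the inputs.
#' @examples
#' couplingDegree(0.2, 0.8)   # 2*sqrt(0.16)/1 = 0.8
#' @export
couplingDegree <- function(veg, sm, form = c("sqrt", "harmonic")) {
  form <- match.arg(form)
  if (is(veg, "RasterGrid") && is(sm, "RasterGrid"))
    assertSameGeometry(veg, sm)
  v <- asValues(veg); s <- asValues(sm)
  checkUnit(v, "veg"); checkUnit(s, "sm")
  den <- v + s
  C <- switch(form,
              sqrt = 2 * sqrt(v * s) / den,
              harmonic = 2 * v * s / den)
  C[!is.na(den) & den == 0] <- NA_real_
  C <- pmin(1, pmax(0, C))
  wrapLike(C, veg)
}

#' Harmonization index of the two subsystems
#'
#' T = alpha VEG + beta SM, a convex combination of the subsystem
#' scores (alpha + beta = 1, both non-negative). The default
#' alpha = beta = 0.5 treats the two subsystems as equally important.
#'
#' @inheritParams couplingDegree
#' @param alpha,beta subsystem weights.
#' @return harmonization index, same container type as the inputs.
#' @export
harmonization <- function(veg, sm, alpha = 0.5, beta = 1 - alpha) {
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  if (is(veg, "RasterGrid") && is(sm, "RasterGrid"))
    assertSameGeometry(veg, sm)
  v <- asValues(veg); s <- asValues(sm)
  checkUnit(v, "veg"); checkUnit(s, "sm")
  wrapLike(alpha * v + beta * s, veg)
}

#' Coupling coordination degree
#'
#' D = sqrt(C x T): the geometric mean of the coupling degree and the
#' harmonization index, summarizing both the balance and the joint
#' level of the two subsystems. Monotone non-decreasing in each
#' argument and bounded in [0, 1] for [0, 1] inputs.
#'
#' @param C coupling degree in [0, 1].
#' @param T harmonization index in [0, 1].
#' @return coupling coordination degree, same container type.
#' @examples
#' couplingCoordination(1, 0.64)   # 0.8
#' @export
couplingCoordination <- function(C, T) {
  if (is(C, "RasterGrid") && is(T, "RasterGrid"))
    assertSameGeometry(C, T)
  cv <- asValues(C); tv <- asValues(T)
  checkUnit(cv, "C"); checkUnit(tv, "T")
  wrapLike(sqrt(pmax(0, cv) * pmax(0, tv)), C)
}

#' Ordinal class labels of the coupling coordination degree
#'
#' Five equal-width levels on (0, 1]:
#' (0, 0.2] Extreme Disorder; (0.2, 0.4] Mild Disorder;
#' (0.4, 0.6] Barely Coordinated; (0.6, 0.8] Moderately Coordinated;
#' (0.8, 1.0] Highly Coordinated.
#'
#' @return character vector of the five labels, in order.
#' @export
ccdLevels <- function() c("Extreme Disorder", "Mild Disorder",
                          "Barely Coordinated", "Moderately Coordinated",
                          "Highly Coordinated")

#' Classify the coupling coordination degree into five levels
#'
#' Half-open equal intervals (low, high]; the boundary value belongs to
#' the lower interval (D = 0.8 is Moderately Coordinated). D = 0 is
#' assigned to Extreme Disorder by convention (noted with a message).
#'
#' @param D coupling coordination values in [0, 1]
#'   ([RasterGrid-class] or numeric).
#' @return integer classes 1..5 (same container type); see
#'   [ccdLevels()] for labels.
#' @export
classifyCCD <- function(D) {
  d <- asValues(D)
  if (any(d < -1e-9 | d > 1 + 1e-9, na.rm = TRUE))
    stop("D values must lie in [0, 1]")
  if (any(!is.na(d) & d == 0))
    message("classifyCCD: D = 0 assigned to Extreme Disorder")
  cls <- pmin(5L, pmax(1L, as.integer(ceiling(d / 0.2))))
  cls[is.na(d)] <- NA_integer_
  if (is(D, "RasterGrid"))
    rasterGrid(cls + 0, geometry(D))  # keep numeric storage for grids
  else cls
}

#' Full coupling-coordination mapping of two subsystem rasters
#'
#' Optionally min-max rescales the two input grids to [0, 1] (the
#' subsystem "evaluation function" convention), then computes the
#' coupling degree C, harmonization index T, coordination degree D and
#' the five-level class map.
#'
#' @param veg,sm [RasterGrid-class] subsystem grids on a shared
#'   geometry.
#' @param alpha vegetation weight of the harmonization index
#'   (beta = 1 - alpha).
#' @param form coupling form, see [couplingDegree()].
#' @param rescale min-max rescale the inputs first (default TRUE; set
#'   FALSE when the grids are already subsystem scores in [0, 1]).
#' @return a [CouplingMaps-class].
#' @export
couplingMaps <- function(veg, sm, alpha = 0.5, form = c("sqrt", "harmonic"),
                         rescale = TRUE) {
  form <- match.arg(form)
  assertSameGeometry(veg, sm)
  if (rescale) { veg <- minMaxRescale(veg); sm <- minMaxRescale(sm) }
  C <- couplingDegree(veg, sm, form = form)
  Tx <- harmonization(veg, sm, alpha = alpha)
  D <- couplingCoordination(C, Tx)
  cls <- classifyCCD(D)
  new("CouplingMaps", cGrid = gridValues(C), tGrid = gridValues(Tx),
      dGrid = gridValues(D),
      classGrid = matrix(as.integer(gridValues(cls)),
                         nrow(gridValues(cls))),
      alpha = alpha, beta = 1 - alpha, form = form, geometry = geometry(veg))
}

#' Area proportion of each coupling-coordination class
#'
#' Fractions of classified basin pixels in each of the five levels
#' (named by [ccdLevels()]); the fractions sum to 1.
#'
#' @param x a [CouplingMaps-class], or an integer class grid/vector
#'   with codes 1..5.
#' @return named numeric of length 5.
#' @export
classAreaProportions <- function(x) {
  cls <- if (is(x, "CouplingMaps")) x@classGrid[basinMask(geometry(x))]
         else if (is(x, "RasterGrid")) gridValues(x)[basinMask(x)]
         else x
  cls <- cls[!is.na(cls)]
  if (!length(cls)) stop("no classified pixels")
  out <- vapply(1:5, function(k) mean(cls == k), numeric(1))
  names(out) <- ccdLevels()
  out
}
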