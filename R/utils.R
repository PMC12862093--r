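# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage child seed fanned out from a global seed, kept
# inside the 32-bit integer range.
childSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(geometry = 11L, samples = 23L, bands = 37L, drivers = 41L,
               split = 53L, series = 61L, forest = 71L, misc = 83L)
  off <- offsets[[stage]]
  (as.integer(seed) * 7919L + off * 104729L) %% 2147483111L
}

clip01 <- function(x) pmin(pmax(x, 0), 1)  # arg order keeps dim attributes

#' Construct a RasterGrid
#'
#' Wraps a value matrix (or a single value, recycled) on a basin
#' geometry; cells outside the basin mask are forced to NA.
#'
#' @param values numeric matrix matching the geometry, or a single
#'   number.
#' @param geom a [BasinGeometry-class].
#' @return a [RasterGrid-class].
#' @export
rasterGrid <- function(values, geom) {
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), geom@nRows, geom@nCols)
  else if (!is.matrix(values) &&
           length(values) == geom@nRows * geom@nCols)
    values <- matrix(as.numeric(values), geom@nRows, geom@nCols)
  values[!geom@mask] <- NA_real_
  new("RasterGrid", values = values, geometry = geom)
}

#' Test or assert that two objects share a basin geometry
#'
#' @param a,b objects with a [geometry()] method.
#' @return \code{sameGeometry} returns TRUE/FALSE;
#'   \code{assertSameGeometry} raises an error naming both geometries on
#'   mismatch, invisibly TRUE otherwise.
#' @export
sameGeometry <- function(a, b) {
  ga <- geometry(a); gb <- geometry(b)
  identical(dim(ga), dim(gb)) &&
    isTRUE(all.equal(ga@cellSize, gb@cellSize)) &&
    isTRUE(all.equal(ga@origin, gb@origin)) &&
    identical(ga@mask, gb@mask)
}

#' @rdname sameGeometry
#' @export
assertSameGeometry <- function(a, b) {
  if (!sameGeometry(a, b)) {
    ga <- geometry(a); gb <- geometry(b)
    stop(sprintf(
      "geometry mismatch: %dx%d @%.6g m origin (%g, %g) vs %dx%d @%.6g m origin (%g, %g)",
      ga@nRows, ga@nCols, ga@cellSize, ga@origin[1], ga@origin[2],
      gb@nRows, gb@nCols, gb@cellSize, gb@origin[1], gb@origin[2]))
  }
  invisible(TRUE)
}

#' Min-max rescale a raster to [0, 1] over basin cells
#'
#' Used to put subsystem scores on the [0, 1] scale the coupling model
#' requires. A constant grid maps to 0.5 (no information; mid-scale).
#'
#' @param grid a [RasterGrid-class].
#' @return a [RasterGrid-class] with values in [0, 1].
#' @export
minMaxRescale <- function(grid) {
  v <- gridValues(grid)
  ok <- basinMask(grid) & !is.na(v)
  rng <- range(v[ok])
  out <- v
  if (diff(rng) < .Machine$double.eps) out[ok] <- 0.5
  else out[ok] <- (v[ok] - rng[1]) / diff(rng)
  rasterGrid(out, geometry(grid))
}

# Map-coordinate centres of all cells; row 1 = north.
cellCenters <- function(geom) {
  x <- geom@origin[1] + (seq_len(geom@nCols) - 0.5) * geom@cellSize
  y <- geom@origin[2] + (geom@nRows - seq_len(geom@nRows) + 0.5) * geom@cellSize
  list(x = x, y = y)
}

# Fraction of southness per row (0 at north edge, 1 at south edge).
southness <- function(geom) {
  (seq_len(geom@nRows) - 0.5) / geom@nRows
}

# Smooth Gaussian-like random field: white noise on a coarse lattice,
# bilinearly interpolated to the full grid. `range` is the coarse knot
# spacing in cells (larger = smoother).
smoothField <- function(nRows, nCols, range = 16, sd = 1) {
  nr <- max(2L, ceiling(nRows / range) + 1L)
  nc <- max(2L, ceiling(nCols / range) + 1L)
  knots <- matrix(rnorm(nr * nc, sd = sd), nr, nc)
  ri <- seq(1, nr, length.out = nRows)
  ci <- seq(1, nc, length.out = nCols)
  r0 <- pmin(floor(ri), nr - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), nc - 1L); fc <- ci - c0
  a <- knots[cbind(rep(r0, nCols), rep(c0, each = nRows))]
  b <- knots[cbind(rep(r0, nCols), rep(c0 + 1L, each = nRows))]
  d <- knots[cbind(rep(r0 + 1L, nCols), rep(c0, each = nRows))]
  e <- knots[cbind(rep(r0 + 1L, nCols), rep(c0 + 1L, each = nRows))]
  wr <- rep(fr, nCols); wc <- rep(fc, each = nRows)
  matrix(a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc +
         d * wr * (1 - wc) + e * wr * wc, nRows, nCols)
}

# Moore-Penrose solve via SVD; equals solve(A, b) for full-rank A but
# tolerates exactly collinear indicators (zero singular values dropped).
pseudoSolve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) %*% b / sv$d[keep])
}
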