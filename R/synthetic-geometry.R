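#' Generate a synthetic basin geometry
#'
#' Builds an irregular, connected basin mask on a regular grid: an
#' ellipse centred in the grid whose boundary radius is perturbed by a
#' low-order random harmonic, mimicking a watershed outline. The mask
#' always covers at least half of the grid and is star-shaped with
#' respect to the centre (hence connected).
#'
#' @param nRows,nCols grid dimensions, both >= 8.
#' @param cellSize cell edge length in metres (default 20, the working
#'   resolution of the resampled satellite grids).
#' @param seed integer seed; the same seed reproduces the identical
#'   mask.
#' @param origin map coordinate (x, y) of the lower-left corner.
#' @return a [BasinGeometry-class].
#' @examples
#' g <- generateGeometry(64, 64, seed = 1)
#' mean(basinMask(g))   # fraction of inside-basin cells, >= 0.5
#' @export
generateGeometry <- function(nRows, nCols, cellSize = 20, seed = NULL,
                             origin = c(0, 0)) {
  if (nRows < 8 || nCols < 8)
    stop("grid dimensions must be at least 8 x 8")
  withSeed(if (is.null(seed)) NULL else childSeed(seed, "geometry"), {
    # unit-square cell centres
    u <- (seq_len(nCols) - 0.5) / nCols
    v <- (seq_len(nRows) - 0.5) / nRows
    du <- outer(rep(1, nRows), u - 0.5)
    dv <- outer(v - 0.5, rep(1, nCols))
    r <- sqrt((du / 0.55)^2 + (dv / 0.55)^2)
    theta <- atan2(dv, du)
    cf <- rnorm(4)
    cf <- cf / max(1, sum(abs(cf)))  # keeps boundary within +/- 18%
    b <- 1 + 0.18 * (cf[1] * cos(theta) + cf[2] * sin(theta) +
                     cf[3] * cos(2 * theta) + cf[4] * sin(2 * theta))
    mask <- r <= b
    new("BasinGeometry", nRows = as.integer(nRows), nCols = as.integer(nCols),
        cellSize = as.numeric(cellSize), origin = as.numeric(origin),
        mask = mask)
  })
}
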