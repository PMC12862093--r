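#' Spearman rank correlation with t-based significance for one pixel
#'
#' The coefficient is the Pearson correlation of the mid-ranks of the
#' two series (the standard tie handling). The two-sided p-value comes
#' from t = rho sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of
#' freedom; |rho| = 1 gives p = 0. A constant series has no ranks to
#' correlate and yields NA (nodata).
#'
#' @param x,y numeric series of equal length n >= 3 (pairs with missing
#'   values are dropped first).
#' @return named numeric c(rho, p, n).
#' @export
spearmanPixel <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(c(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rx, ry)
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) >= 1 - 1e-12) 0
       else 2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  c(rho = rho, p = p, n = n)
}

#' Per-pixel Spearman correlation between two raster time series
#'
#' Applies [spearmanPixel()] to every basin pixel of two aligned stacks
#' (same geometry and identical time axes) and classifies each pixel at
#' level \code{alpha} into significant-positive, significant-negative
#' or non-significant. By default raw p-values are mapped (matching
#' per-pixel significance mapping practice); \code{adjust = "BH"}
#' applies a Benjamini-Hochberg correction across basin pixels first.
#'
#' @param smStack,vegStack aligned [TimeSeriesStack-class] objects.
#' @param alpha significance level (default 0.05).
#' @param adjust "none" (default) or "BH".
#' @return a [CorrelationMaps-class].
#' @export
correlateStacks <- function(smStack, vegStack, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  assertSameGeometry(smStack, vegStack)
  if (!identical(smStack@times, vegStack@times))
    stop("time axes differ between the two stacks")
  g <- geometry(smStack)
  a1 <- stackArray(smStack); a2 <- stackArray(vegStack)
  rho <- p <- n <- matrix(NA_real_, g@nRows, g@nCols)
  idx <- which(g@mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    res <- spearmanPixel(a1[i, j, ], a2[i, j, ])
    rho[i, j] <- res[["rho"]]; p[i, j] <- res[["p"]]; n[i, j] <- res[["n"]]
  }
  if (adjust == "BH") {
    sel <- g@mask & !is.na(p)
    p[sel] <- p.adjust(p[sel], method = "BH")
  }
  cls <- matrix(NA_integer_, g@nRows, g@nCols)
  ok <- g@mask & !is.na(rho)
  cls[ok] <- 3L
  cls[ok & p < alpha & rho > 0] <- 1L
  cls[ok & p < alpha & rho < 0] <- 2L
  new("CorrelationMaps", rho = rho, p = p, n = n, classGrid = cls,
      alpha = alpha, geometry = g)
}

#' Area proportions of the significance classes
#'
#' Fractions of classified basin pixels falling in each significance
#' class; the three fractions sum to 1.
#'
#' @param x a [CorrelationMaps-class].
#' @return named numeric c(sig_pos, sig_neg, nonsig).
#' @export
areaProportions <- function(x) {
  stopifnot(is(x, "CorrelationMaps"))
  cls <- x@classGrid[basinMask(geometry(x))]
  cls <- cls[!is.na(cls)]
  if (!length(cls)) stop("no classified pixels")
  c(sig_pos = mean(cls == 1L), sig_neg = mean(cls == 2L),
    nonsig = mean(cls == 3L))
}
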