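#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO compares observed correlations with anti-image partial
#' correlations: sum(r^2 off-diagonal) / (sum(r^2) + sum(q^2)), where
#' q are the partial correlations obtained from the inverse correlation
#' matrix. Values near 1 indicate strong shared variance; below 0.5 the
#' indicator set is unsuitable for factor extraction. An identity
#' correlation matrix has no shared variance; by convention the measure
#' is 0 there (with a warning).
#'
#' @param R correlation matrix (invertible).
#' @return overall KMO in [0, 1].
#' @export
kmo <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  inv <- tryCatch(solve(R),
                  error = function(e) stop("singular correlation matrix"))
  d <- 1 / sqrt(diag(inv))
  Q <- -inv * outer(d, d)
  off <- row(R) != col(R)
  sr2 <- sum(R[off]^2)
  sq2 <- sum(Q[off]^2)
  if (sr2 + sq2 < .Machine$double.eps) {
    warning("kmo: no off-diagonal correlation; measure undefined, returning 0")
    return(0)
  }
  sr2 / (sr2 + sq2)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' chi2 = -(n - 1 - (2p + 5)/6) log|R| on p(p - 1)/2 degrees of
#' freedom.
#'
#' @param R correlation matrix.
#' @param n number of observations behind R (must exceed p).
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
bartlettSphericity <- function(R, n) {
  p <- ncol(R)
  if (n <= p) stop("n must exceed the number of variables")
  dR <- det(R)
  if (dR <= 0) stop("non-positive determinant: correlation matrix invalid")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(dR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
}

# deterministic sign convention: each loading column sums positive
fixSigns <- function(L) {
  for (k in seq_len(ncol(L))) {
    s <- sum(L[, k])
    if (s < 0 || (s == 0 && L[which.max(abs(L[, k])), k] < 0))
      L[, k] <- -L[, k]
  }
  L
}

#' Correlation-matrix PCA for composite-indicator construction
#'
#' Eigen-decomposes the indicator correlation matrix; loadings are
#' eigenvectors scaled by the square root of their eigenvalue.
#' Components are retained by the Kaiser rule (eigenvalue > 1),
#' extended while the cumulative explained variance is below
#' \code{cumTarget} percent. Retained loadings are varimax-rotated
#' (with Kaiser normalization) when two or more components are kept;
#' rotated components are ordered by decreasing rotated sum of squared
#' loadings. Component score coefficients use the regression method,
#' solve(R) \%*\% rotated loadings. Communalities are the per-indicator
#' sums of squared retained loadings (invariant under rotation).
#'
#' @param x numeric matrix/data.frame of observations x indicators
#'   (z-scored internally), or a correlation matrix if
#'   \code{correlation = TRUE}.
#' @param correlation set TRUE when \code{x} is already a correlation
#'   matrix.
#' @param nRetain override the retention rule with a fixed component
#'   count.
#' @param cumTarget cumulative-variance target (percent) extending the
#'   Kaiser rule (default 90).
#' @return a [PcaResult-class].
#' @export
indicatorPca <- function(x, correlation = FALSE, nRetain = NULL,
                         cumTarget = 90) {
  if (correlation) {
    R <- as.matrix(x)
  } else {
    x <- as.matrix(x)
    if (nrow(x) < ncol(x))
      stop("fewer observations than indicators")
    R <- cor(x)
  }
  p <- ncol(R)
  nm <- colnames(R)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  ev <- eigen(R, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  L <- fixSigns(ev$vectors %*% diag(sqrt(lam), p))
  dimnames(L) <- list(nm, paste0("PC", seq_len(p)))
  variancePct <- 100 * lam / p
  cumulativePct <- cumsum(variancePct)
  if (is.null(nRetain)) {
    nRetain <- max(1L, sum(lam > 1))
    while (nRetain < p && cumulativePct[nRetain] < cumTarget)
      nRetain <- nRetain + 1L
  }
  nRetain <- as.integer(nRetain)
  Lr <- L[, seq_len(nRetain), drop = FALSE]
  if (nRetain >= 2L) {
    rot <- varimax(Lr, normalize = TRUE)
    Lr <- Lr %*% rot$rotmat
    ss <- colSums(Lr^2)
    Lr <- fixSigns(Lr[, order(-ss), drop = FALSE])
  }
  rotatedSS <- colSums(Lr^2)
  colnames(Lr) <- paste0("F", seq_len(nRetain))
  names(rotatedSS) <- colnames(Lr)
  score <- pseudoSolve(R, Lr)  # tolerant of degenerate correlation matrices
  dimnames(score) <- dimnames(Lr)
  comm <- rowSums(L[, seq_len(nRetain), drop = FALSE]^2)
  names(comm) <- nm
  new("PcaResult", eigenvalues = lam, variancePct = variancePct,
      cumulativePct = cumulativePct, loadings = L, rotatedLoadings = Lr,
      rotatedSS = rotatedSS, scoreCoefficients = score,
      communalities = comm, nRetained = nRetain)
}

#' Communalities from a loading matrix
#'
#' Row sums of squared loadings: the indicator variance explained by
#' the retained components.
#'
#' @param loadings indicator x component loading matrix.
#' @return named numeric vector.
#' @export
communalityFromLoadings <- function(loadings) {
  rowSums(as.matrix(loadings)^2)
}

#' Composite-index weights from component score coefficients
#'
#' Each indicator's combined coefficient is the score-coefficient
#' matrix weighted by the components' shares of the rotated sums of
#' squared loadings (lambda_k / sum lambda); the combined coefficients
#' are then normalized to sum to one. A negative combined coefficient
#' triggers a warning (normalization still runs over the raw values).
#'
#' @param x a [PcaResult-class], or an indicator x component matrix of
#'   score coefficients.
#' @param rotatedSS rotated sums of squared loadings (required when
#'   \code{x} is a plain matrix).
#' @return named weights summing to 1.
#' @examples
#' # two printed component-score equations combined into final weights
#' S <- matrix(c(0.570, 0.637, -0.367, -0.130, -0.245, 1.159), 3, 2,
#'             dimnames = list(c("NPP", "LAI", "ARVI"), NULL))
#' compositeWeights(S, rotatedSS = c(1.778, 1.083))
#' @export
compositeWeights <- function(x, rotatedSS = NULL) {
  if (is(x, "PcaResult")) {
    S <- x@scoreCoefficients
    lam <- x@rotatedSS
  } else {
    S <- as.matrix(x)
    if (is.null(rotatedSS)) stop("rotatedSS required with a plain matrix")
    lam <- rotatedSS
  }
  stopifnot(length(lam) == ncol(S), all(lam > 0))
  combined <- as.vector(S %*% (lam / sum(lam)))
  names(combined) <- rownames(S)
  if (any(combined < 0))
    warning("compositeWeights: negative combined coefficient; ",
            "normalizing over raw values")
  combined / sum(combined)
}

#' Select the spectral index best suited to join NPP and LAI
#'
#' For each candidate index, assembles the triple (candidate, NPP,
#' LAI), computes the pairwise correlations, the KMO measure and
#' Bartlett's test, and gates on (i) Bartlett p < \code{alpha},
#' (ii) max |r| of the candidate with NPP or LAI above \code{corGate},
#' (iii) KMO >= \code{kmoGate}. Among passing candidates the one with
#' the highest KMO wins; if none passes, the best-KMO candidate is
#' returned flagged.
#'
#' @param candidates named list (or data.frame) of candidate index
#'   values at the evaluation points.
#' @param npp,lai vectors of NPP and LAI at the same points.
#' @param corGate correlation gate (default 0.6).
#' @param kmoGate KMO gate (default 0.5).
#' @param alpha Bartlett significance level (default 0.05).
#' @return list: \code{index} (chosen name), \code{passedGates},
#'   \code{table} (per-candidate diagnostics).
#' @export
selectBestIndex <- function(candidates, npp, lai, corGate = 0.6,
                            kmoGate = 0.5, alpha = 0.05) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 2) stop("need at least two candidate indices")
  rows <- lapply(names(candidates), function(nm) {
    M <- cbind(cand = candidates[[nm]], NPP = npp, LAI = lai)
    R <- cor(M)
    k <- kmo(R)
    b <- bartlettSphericity(R, nrow(M))
    data.frame(candidate = nm, kmo = k, bartlettP = b$p,
               rNPP = R["cand", "NPP"], rLAI = R["cand", "LAI"])
  })
  tab <- do.call(rbind, rows)
  tab$passed <- tab$bartlettP < alpha & tab$kmo >= kmoGate &
    pmax(abs(tab$rNPP), abs(tab$rLAI)) > corGate
  pool <- if (any(tab$passed)) tab[tab$passed, ] else tab
  if (!any(tab$passed))
    message("selectBestIndex: no candidate passed all gates; ",
            "best-KMO candidate chosen")
  list(index = pool$candidate[which.max(pool$kmo)],
       passedGates = any(tab$passed), table = tab)
}

#' Composite vegetation index raster
#'
#' Min-max rescales each indicator grid to [0, 1] over basin cells and
#' forms the cellwise weighted sum with the composite weights, so the
#' output is itself in [0, 1] and directly usable as the vegetation
#' subsystem score of the coupling model.
#'
#' @param weights named weights (summing to 1), e.g. from
#'   [compositeWeights()].
#' @param grids named list of [RasterGrid-class], one per weight name.
#' @return a [RasterGrid-class].
#' @export
vegRaster <- function(weights, grids) {
  miss <- setdiff(names(weights), names(grids))
  if (length(miss))
    stop(sprintf("missing indicator grid(s): %s",
                 paste(miss, collapse = ", ")))
  ref <- grids[[names(weights)[1]]]
  out <- 0
  for (nm in names(weights)) {
    assertSameGeometry(ref, grids[[nm]])
    out <- out + weights[[nm]] * gridValues(minMaxRescale(grids[[nm]]))
  }
  rasterGrid(out, geometry(ref))
}
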