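#' Gini impurity of a node
#'
#' 1 - sum(p_j^2) over the class shares of the node; 0 for a pure node
#' and at most 1 - 1/k for k classes.
#'
#' @param counts non-negative class counts (total >= 1).
#' @return impurity in [0, 1 - 1/k].
#' @export
giniImpurity <- function(counts) {
  if (sum(counts) < 1) stop("empty node")
  if (any(counts < 0)) stop("negative counts")
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Count-weighted Gini decrease of a split
#'
#' gain = Gini(parent) - (n_l/n) Gini(left) - (n_r/n) Gini(right).
#' Child impurities are weighted by their sample shares, the standard
#' CART decrease; by concavity of the Gini index the gain is always
#' non-negative.
#'
#' @param parent,left,right class-count vectors; left + right must
#'   equal parent.
#' @return the impurity decrease (>= 0).
#' @export
giniGain <- function(parent, left, right) {
  if (!isTRUE(all.equal(unname(parent), unname(left + right))))
    stop("left + right counts must equal parent counts")
  n <- sum(parent)
  giniImpurity(parent) - sum(left) / n * giniImpurity(left) -
    sum(right) / n * giniImpurity(right)
}

#' Fit a Gini-importance CART forest
#'
#' Grows \code{nTrees} CART trees on bootstrap resamples, choosing at
#' each node the best impurity-decrease split among \code{mtry}
#' randomly drawn features (thresholds at midpoints of distinct
#' consecutive values; exactly tied gains keep the first candidate in
#' the drawn feature order, so single-tree full-mtry fits are
#' deterministic while forest ties stay unbiased). Per-feature
#' importance sums, over all splits on that feature in all trees, the
#' impurity decrease weighted by the node sample fraction (the
#' standard forest accumulation), and is normalized to shares summing
#' to 1.
#'
#' For a factor response the impurity is the Gini index
#' (classification, the default use); for a numeric response the
#' variance impurity is used (regression mode).
#'
#' @param x numeric matrix or data.frame of features.
#' @param y response: factor (classification) or numeric (regression).
#' @param nTrees number of trees (default 500).
#' @param mtry features tried per node (default floor(sqrt(p))).
#' @param minLeaf minimum samples per leaf (default 5).
#' @param maxDepth maximum tree depth, 0 = unlimited.
#' @param bootstrap resample with replacement per tree (default TRUE;
#'   FALSE fits each tree on the full sample, used for single-tree
#'   analysis).
#' @param seed integer seed.
#' @return object of class \code{giniForest}: list with
#'   \code{importance} (data.frame: feature, giniDecrease, share,
#'   rank), \code{trees}, \code{mode}, \code{levels}, \code{mtry},
#'   \code{nTrees}.
#' @export
fitGiniForest <- function(x, y, nTrees = 500, mtry = NULL, minLeaf = 5,
                          maxDepth = 0, bootstrap = TRUE, seed = NULL) {
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  if (nrow(x) < 50) stop("need at least 50 samples")
  if (is.factor(y) || is.character(y) || is.integer(y)) {
    y <- factor(y)
    if (nlevels(droplevels(y)) < 2)
      stop("single-class labels: nothing to split")
    lev <- levels(y)
    yNum <- as.numeric(y) - 1
    nClass <- length(lev)
    mode <- "classification"
  } else {
    lev <- NULL
    yNum <- as.numeric(y)
    nClass <- 0L
    mode <- "regression"
  }
  stopifnot(length(yNum) == nrow(x), all(is.finite(x)),
            all(is.finite(yNum)))
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  res <- withSeed(if (is.null(seed)) NULL else childSeed(seed, "forest"),
                  .cppGiniForest(x, yNum, as.integer(nClass),
                                 as.integer(nTrees), as.integer(mtry),
                                 as.integer(minLeaf), as.integer(maxDepth),
                                 isTRUE(bootstrap)))
  imp <- res$importance
  total <- sum(imp)
  share <- if (total > 0) imp / total else rep(1 / p, p)
  featNames <- colnames(x)
  if (is.null(featNames)) featNames <- paste0("X", seq_len(p))
  tab <- data.frame(feature = featNames, giniDecrease = imp,
                    share = share)
  tab$rank <- rank(-tab$share, ties.method = "min")
  structure(list(importance = tab, trees = res$trees, mode = mode,
                 levels = lev, mtry = mtry, nTrees = nTrees),
            class = "giniForest")
}

#' @export
print.giniForest <- function(x, ...) {
  cat(sprintf("giniForest: %d trees (%s), mtry = %d\n", x$nTrees,
              x$mode, x$mtry))
  print(x$importance[order(x$importance$rank), ], row.names = FALSE)
  invisible(x)
}

#' @method predict giniForest
#' @export
predict.giniForest <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata))
  storage.mode(x) <- "double"
  out <- .cppForestPredict(object$trees, x,
                           if (object$mode == "classification")
                             length(object$levels) else 0L)
  if (object$mode == "classification")
    factor(object$levels[out + 1], levels = object$levels)
  else out
}

#' Rank driver importance for the coupling coordination degree
#'
#' Assembles a per-pixel table of the eight driver values and the
#' coupling coordination degree, discretizes D into the five ordinal
#' classes (the classification target of the Gini forest; a
#' variance-impurity regression on continuous D is available with
#' \code{mode = "regression"}), optionally subsamples pixels to bound
#' memory, and fits [fitGiniForest()].
#'
#' @param drivers named list of driver [RasterGrid-class] objects (or
#'   the \code{drivers} element of [generateDriverStack()]).
#' @param dGrid [RasterGrid-class] of the coupling coordination
#'   degree.
#' @param nTrees,mtry,minLeaf forest hyperparameters (defaults 500,
#'   floor(sqrt(p)) = 2 for the eight drivers, 5).
#' @param maxPixels random pixel subsample cap (default 50000).
#' @param mode "classification" (default) or "regression".
#' @param seed integer seed.
#' @return a \code{giniForest}; its \code{importance} table carries the
#'   normalized shares and ranking.
#' @export
driverImportance <- function(drivers, dGrid, nTrees = 500, mtry = NULL,
                             minLeaf = 5, maxPixels = 50000,
                             mode = c("classification", "regression"),
                             seed = NULL) {
  mode <- match.arg(mode)
  for (g in drivers) assertSameGeometry(g, dGrid)
  mask <- basinMask(dGrid)
  d <- gridValues(dGrid)
  X <- vapply(drivers, function(g) gridValues(g)[mask], numeric(sum(mask)))
  dv <- d[mask]
  ok <- stats::complete.cases(X) & !is.na(dv)
  X <- X[ok, , drop = FALSE]; dv <- dv[ok]
  if (nrow(X) > maxPixels) {
    pick <- withSeed(if (is.null(seed)) NULL else childSeed(seed, "misc"),
                     sample(nrow(X), maxPixels))
    X <- X[pick, , drop = FALSE]; dv <- dv[pick]
  }
  y <- if (mode == "classification")
    factor(classifyCCD(dv), levels = 1:5, labels = ccdLevels())
  else dv
  if (mode == "classification" && nlevels(droplevels(y)) < 2)
    stop("coordination classes are degenerate (single class present)")
  fitGiniForest(X, y, nTrees = nTrees, mtry = mtry, minLeaf = minLeaf,
                seed = seed)
}

#' Consistency of importance rankings across depth layers
#'
#' Kendall's tau between the per-depth importance shares; full
#' consistency is flagged when every pairwise tau equals 1.
#'
#' @param reports named list (>= 2) of importance tables from
#'   [fitGiniForest()]/[driverImportance()] (or named share vectors)
#'   over the same feature set.
#' @return list: \code{tau} (pairwise matrix), \code{consistent}
#'   (logical).
#' @export
rankConsistency <- function(reports) {
  if (length(reports) < 2) stop("need at least two reports")
  shares <- lapply(reports, function(r) {
    if (is.data.frame(r)) stats::setNames(r$share, r$feature)
    else if (inherits(r, "giniForest"))
      stats::setNames(r$importance$share, r$importance$feature)
    else r
  })
  feats <- names(shares[[1]])
  if (!all(vapply(shares, function(s) setequal(names(s), feats),
                  logical(1))))
    stop("mismatched feature sets across reports")
  M <- vapply(shares, function(s) s[feats], numeric(length(feats)))
  tau <- cor(M, method = "kendall")
  list(tau = tau, consistent = all(tau >= 1 - 1e-12))
}
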