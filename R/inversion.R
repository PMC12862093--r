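#' Screen candidate predictors by Pearson correlation with the response
#'
#' Computes the Pearson correlation of every candidate column with the
#' response for one depth layer, with the two-sided p-value from the
#' t distribution on n - 2 degrees of freedom, and retains predictors
#' significant at \code{alpha}. Constant predictors are excluded with a
#' message. The returned table is ranked by |r|.
#'
#' @param table a sample table from [generateSoilSamples()] (or of the
#'   same shape).
#' @param depth depth-layer label from [depthLayers()].
#' @param alpha significance level (default 0.05).
#' @param response response column (default "SM").
#' @param candidates candidate predictor columns; default: every
#'   numeric column except identifiers, coordinates and the response.
#' @return data.frame with columns \code{predictor, r, p, retained}.
#' @export
screenPredictors <- function(table, depth, alpha = 0.05, response = "SM",
                             candidates = NULL) {
  d <- table[table$depth == depth, , drop = FALSE]
  if (nrow(d) < 10L) stop("need at least 10 rows for the depth layer")
  if (is.null(candidates)) {
    num <- names(d)[vapply(d, is.numeric, logical(1))]
    candidates <- setdiff(num, c("site", "x", "y", response))
  }
  y <- d[[response]]
  rows <- lapply(candidates, function(nm) {
    v <- d[[nm]]
    if (sd(v) < .Machine$double.eps) {
      message(sprintf("screenPredictors: '%s' is constant, excluded", nm))
      return(NULL)
    }
    r <- cor(v, y)
    n <- length(v)
    if (abs(r) >= 1) p <- 0
    else {
      t <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(-abs(t), n - 2)
    }
    data.frame(predictor = nm, r = r, p = p, retained = p < alpha)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$r)), ]
  rownames(out) <- NULL
  out
}

#' Split a sample table into modeling and validation sets by site
#'
#' Sites are shuffled with the given seed and partitioned
#' \code{ratio}:1 (floor-based), keeping all depth layers of a site on
#' the same side: 170 sites at 4:1 give 136 modeling and 34 validation
#' sites.
#'
#' @param table sample table.
#' @param ratio modeling:validation ratio (default 4).
#' @param seed integer seed; the same seed reproduces the partition.
#' @return list with data.frames \code{train} and \code{valid}.
#' @export
splitSamples <- function(table, ratio = 4, seed = NULL) {
  sites <- unique(table$site)
  if (length(sites) < ratio + 1)
    stop("too few sites for the requested split ratio")
  nTrain <- floor(length(sites) * ratio / (ratio + 1))
  withSeed(if (is.null(seed)) NULL else childSeed(seed, "split"), {
    shuffled <- sample(sites)
    trainSites <- shuffled[seq_len(nTrain)]
    list(train = table[table$site %in% trainSites, , drop = FALSE],
         valid = table[!table$site %in% trainSites, , drop = FALSE])
  })
}

# ---- stepwise multiple linear regression (partial-F entry/removal) ----

#' Fit soil-moisture regressions for one depth layer
#'
#' Three interchangeable fitters returning a [FittedModel-class]:
#'
#' \code{fitSMLR} performs forward-backward stepwise selection on
#' partial-F p-values (enter while the best candidate has p <
#' \code{pEnter}, remove while the worst retained term has p >=
#' \code{pRemove}), the classical significance-gated stepwise
#' procedure. If no predictor enters, an intercept-only model is
#' returned with a message. Selection stops once the fit is numerically
#' saturated (R-squared within 1e-12 of 1).
#'
#' \code{fitRidge} solves the L2-penalized least-squares problem in
#' closed form on standardized predictors, choosing the penalty by
#' k-fold cross-validated RMSE over a log-spaced grid; coefficients are
#' returned on the original scale. A zero penalty on a full-rank design
#' reproduces ordinary least squares; a singular design with zero
#' penalty falls back to the smallest positive grid value with a
#' message.
#'
#' \code{fitPLSR} fits partial least squares (NIPALS) on standardized
#' predictors. The component count is chosen by k-fold cross-validation
#' with the one-standard-error rule (the smallest count whose CV error
#' is within one standard error of the minimum), the usual guard
#' against overfitting the component count; with all components on a
#' full-rank design the fit reproduces least squares.
#'
#' @param train training rows (one depth layer).
#' @param predictors character vector of predictor columns (the
#'   screened pool).
#' @param response response column (default "SM").
#' @param depth depth-layer label stored in the model.
#' @param pEnter,pRemove stepwise entry/removal p-value thresholds
#'   (defaults 0.05 / 0.10; pEnter must be < pRemove).
#' @param penaltyGrid ridge penalty grid (lambda of the standardized
#'   problem); may include 0.
#' @param maxComponents maximum PLSR component count (default: design
#'   rank).
#' @param nfolds number of cross-validation folds.
#' @param seed seed for the fold assignment.
#' @return a [FittedModel-class].
#' @name fitters
NULL

#' @rdname fitters
#' @export
fitSMLR <- function(train, predictors, response = "SM",
                    depth = NA_character_, pEnter = 0.05, pRemove = 0.10) {
  if (length(predictors) < 1L) stop("no candidate predictors")
  if (pEnter >= pRemove)
    stop("pEnter must be smaller than pRemove (prevents cycling)")
  d <- train[, c(response, predictors), drop = FALSE]
  current <- character()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 50L) break  # stepwise safety cap
    changed <- FALSE
    fit <- lm(reformulate(if (length(current)) current else "1",
                          response), data = d)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    saturated <- length(current) > 0 && r2 > 1 - 1e-12
    remaining <- setdiff(predictors, current)
    if (length(remaining) && !saturated) {
      a1 <- suppressWarnings(add1(fit, scope = reformulate(c(current,
                                                             remaining)),
                                  test = "F"))
      pv <- a1[["Pr(>F)"]][-1]
      if (any(is.finite(pv)) && min(pv, na.rm = TRUE) < pEnter) {
        current <- c(current, rownames(a1)[-1][which.min(pv)])
        changed <- TRUE
        fit <- lm(reformulate(current, response), data = d)
      }
    }
    if (length(current) > 1L ||
        (length(current) == 1L && !changed)) {
      d1 <- suppressWarnings(drop1(fit, test = "F"))
      pv <- d1[["Pr(>F)"]][-1]
      if (any(is.finite(pv)) && max(pv, na.rm = TRUE) >= pRemove) {
        worst <- rownames(d1)[-1][which.max(pv)]
        current <- setdiff(current, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(current))
    message("fitSMLR: no predictor entered; intercept-only model")
  fit <- lm(reformulate(if (length(current)) current else "1", response),
            data = d)
  cf <- coef(fit)
  new("FittedModel", method = "SMLR", depth = depth,
      intercept = unname(cf[1]),
      coefficients = if (length(current)) cf[-1][current] else
        stats::setNames(numeric(0), character(0)),
      hyper = list(pEnter = pEnter, pRemove = pRemove),
      screened = predictors)
}

ridgeSolve <- function(Z, yc, lambda) {
  p <- ncol(Z)
  solve(crossprod(Z) + diag(lambda, p), crossprod(Z, yc))
}

#' @rdname fitters
#' @export
fitRidge <- function(train, predictors, response = "SM",
                     depth = NA_character_,
                     penaltyGrid = 10^seq(-4, 3, length.out = 29),
                     nfolds = 5, seed = NULL) {
  X <- as.matrix(train[, predictors, drop = FALSE])
  y <- train[[response]]
  mx <- colMeans(X); sx <- apply(X, 2, sd)
  if (any(sx < .Machine$double.eps)) stop("constant predictor in design")
  Z <- scale(X, center = mx, scale = sx)
  my <- mean(y); yc <- y - my
  grid <- sort(unique(penaltyGrid))
  if (length(grid) > 1L) {
    folds <- withSeed(if (is.null(seed)) NULL else childSeed(seed, "misc"),
                      sample(rep_len(seq_len(nfolds), nrow(Z))))
    cvErr <- vapply(grid, function(lam) {
      errs <- vapply(seq_len(nfolds), function(k) {
        tr <- folds != k
        b <- tryCatch(ridgeSolve(Z[tr, , drop = FALSE], yc[tr], lam),
                      error = function(e) NULL)
        if (is.null(b)) return(Inf)
        mean((yc[!tr] - Z[!tr, , drop = FALSE] %*% b)^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    lambda <- grid[which.min(cvErr)]
  } else lambda <- grid
  b <- tryCatch(ridgeSolve(Z, yc, lambda), error = function(e) NULL)
  if (is.null(b)) {
    fallback <- min(penaltyGrid[penaltyGrid > 0])
    message(sprintf(
      "fitRidge: singular design at penalty %.3g; using %.3g", lambda,
      fallback))
    lambda <- fallback
    b <- ridgeSolve(Z, yc, lambda)
  }
  bOrig <- as.vector(b) / sx
  intercept <- my - sum(bOrig * mx)
  new("FittedModel", method = "Ridge", depth = depth,
      intercept = intercept,
      coefficients = stats::setNames(bOrig, predictors),
      hyper = list(penalty = lambda, grid = grid),
      screened = predictors)
}

# NIPALS partial least squares on standardized X, centered y; returns
# coefficients of the standardized problem for `ncomp` components.
plsCoef <- function(Z, yc, ncomp) {
  p <- ncol(Z)
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  Xd <- Z; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    pp <- crossprod(Xd, tt) / tt2
    qq <- sum(yd * tt) / tt2
    W[, a] <- w; P[, a] <- pp; q[a] <- qq
    Xd <- Xd - tt %*% t(pp)
    yd <- yd - tt * qq
  }
  if (ncomp == 0L) return(rep(0, p))
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  as.vector(W %*% solve(crossprod(P, W), q))
}

#' @rdname fitters
#' @export
fitPLSR <- function(train, predictors, response = "SM",
                    depth = NA_character_, maxComponents = NULL,
                    nfolds = 5, seed = NULL) {
  X <- as.matrix(train[, predictors, drop = FALSE])
  y <- train[[response]]
  mx <- colMeans(X); sx <- apply(X, 2, sd)
  if (any(sx < .Machine$double.eps)) stop("constant predictor in design")
  Z <- scale(X, center = mx, scale = sx)
  my <- mean(y); yc <- y - my
  rk <- qr(Z)$rank
  if (is.null(maxComponents)) maxComponents <- rk
  if (maxComponents < 1) stop("maxComponents must be >= 1")
  maxComponents <- min(maxComponents, rk)
  if (maxComponents > 1L) {
    folds <- withSeed(if (is.null(seed)) NULL else childSeed(seed, "misc"),
                      sample(rep_len(seq_len(nfolds), nrow(Z))))
    foldErr <- vapply(seq_len(maxComponents), function(a) {
      vapply(seq_len(nfolds), function(k) {
        tr <- folds != k
        b <- plsCoef(Z[tr, , drop = FALSE], yc[tr], a)
        mean((yc[!tr] - Z[!tr, , drop = FALSE] %*% b)^2)
      }, numeric(1))
    }, numeric(nfolds))
    cvErr <- colMeans(foldErr)
    best <- which.min(cvErr)
    se <- sd(foldErr[, best]) / sqrt(nfolds)
    ncomp <- which(cvErr <= cvErr[best] + se)[1]  # one-SE rule
  } else ncomp <- 1L
  b <- plsCoef(Z, yc, ncomp)
  bOrig <- b / sx
  new("FittedModel", method = "PLSR", depth = depth,
      intercept = my - sum(bOrig * mx),
      coefficients = stats::setNames(bOrig, predictors),
      hyper = list(nComponents = ncomp, maxComponents = maxComponents),
      screened = predictors)
}

#' Predict from a fitted soil-moisture model
#'
#' @param object a [FittedModel-class].
#' @param newdata data.frame containing the model's predictor columns.
#' @param ... unused.
#' @return numeric predictions (unclipped).
#' @export
setMethod("predict", "FittedModel", function(object, newdata, ...) {
  cf <- object@coefficients
  out <- rep(object@intercept, nrow(newdata))
  if (length(cf)) {
    miss <- setdiff(names(cf), names(newdata))
    if (length(miss))
      stop(sprintf("newdata lacks predictor(s): %s",
                   paste(miss, collapse = ", ")))
    out <- out + as.vector(as.matrix(newdata[, names(cf), drop = FALSE]) %*% cf)
  }
  out
})

#' Validation metrics of a prediction
#'
#' \code{regressionMetrics} computes, for measured values x and
#' predictions xhat: R-squared = 1 - SSE/SST, RMSE = sqrt(mean squared
#' error), MAE = mean absolute error, and MAPE = mean(|error /
#' measured|) x 100 (undefined, with a warning, when any measured value
#' is zero). \code{evaluateModel} applies them to a model on a
#' validation set and adds the two-sided p-value of the
#' measured-predicted Pearson correlation (t on n - 2 df).
#'
#' @param measured,predicted numeric vectors.
#' @return \code{regressionMetrics}: named numeric (R2, RMSE, MAE,
#'   MAPE); \code{evaluateModel}: one-row data.frame (method, depth,
#'   R2, RMSE, MAE, MAPE, p, nValid).
#' @export
regressionMetrics <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 1)
  err <- predicted - measured
  sst <- sum((measured - mean(measured))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(err^2) / sst
  mape <- if (any(measured == 0)) {
    warning("MAPE undefined: measured value equal to 0")
    NA_real_
  } else 100 * mean(abs(err / measured))
  c(R2 = r2, RMSE = sqrt(mean(err^2)), MAE = mean(abs(err)), MAPE = mape)
}

#' @rdname regressionMetrics
#' @param model a [FittedModel-class].
#' @param valid validation rows (one depth layer).
#' @param response response column.
#' @export
evaluateModel <- function(model, valid, response = "SM") {
  if (!nrow(valid)) stop("validation set is empty")
  pred <- predict(model, valid)
  m <- regressionMetrics(valid[[response]], pred)
  n <- nrow(valid)
  r <- suppressWarnings(cor(valid[[response]], pred))
  p <- if (!is.finite(r) || n < 3) NA_real_
       else if (abs(r) >= 1) 0
       else 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  data.frame(method = model@method, depth = model@depth,
             R2 = m[["R2"]], RMSE = m[["RMSE"]], MAE = m[["MAE"]],
             MAPE = m[["MAPE"]], p = p, nValid = n)
}

#' Rule-based selection among candidate models
#'
#' Among candidates passing all three error gates (RMSE <
#' \code{rmseMax}, MAE < \code{maeMax}, 0 <= MAPE <= \code{mapeMax}),
#' picks the highest validation R-squared; if none passes, picks the
#' minimum-RMSE candidate and flags it. Ties break by method order
#' SMLR < Ridge < PLSR.
#'
#' @param reports data.frame of [evaluateModel()] rows (one per
#'   candidate).
#' @param rmseMax,maeMax,mapeMax error gates (defaults 0.05, 0.02, 20).
#' @return list: \code{method}, \code{passedGates} (logical),
#'   \code{report} (the chosen row).
#' @export
selectModel <- function(reports, rmseMax = 0.05, maeMax = 0.02,
                        mapeMax = 20) {
  if (!nrow(reports)) stop("no candidate reports")
  ord <- match(reports$method, c("SMLR", "Ridge", "PLSR"))
  reports <- reports[order(ord), , drop = FALSE]
  pass <- reports$RMSE < rmseMax & reports$MAE < maeMax &
    !is.na(reports$MAPE) & reports$MAPE >= 0 & reports$MAPE <= mapeMax
  if (any(pass)) {
    cand <- reports[pass, , drop = FALSE]
    pick <- cand[which.max(cand$R2), , drop = FALSE]
    list(method = pick$method, passedGates = TRUE, report = pick)
  } else {
    pick <- reports[which.min(reports$RMSE), , drop = FALSE]
    message("selectModel: no candidate met the error gates; ",
            "minimum-RMSE model chosen")
    list(method = pick$method, passedGates = FALSE, report = pick)
  }
}

#' Evaluate a fitted model over predictor rasters
#'
#' Applies the linear model cellwise to the named predictor grids,
#' clips the result to the volumetric-fraction range [0, 1] (optional)
#' and propagates nodata: a cell that is nodata in any used predictor
#' is nodata in the output.
#'
#' @param model a [FittedModel-class].
#' @param grids named list of [RasterGrid-class] covering every
#'   retained predictor.
#' @param clip clip predictions to [0, 1] (default TRUE).
#' @return a [RasterGrid-class].
#' @export
predictRaster <- function(model, grids, clip = TRUE) {
  cf <- model@coefficients
  miss <- setdiff(names(cf), names(grids))
  if (length(miss))
    stop(sprintf("missing predictor grid(s): %s",
                 paste(miss, collapse = ", ")))
  if (!length(cf)) stop("model has no retained predictors")
  ref <- grids[[names(cf)[1]]]
  out <- matrix(model@intercept, nrow(gridValues(ref)),
                ncol(gridValues(ref)))
  for (nm in names(cf)) {
    assertSameGeometry(ref, grids[[nm]])
    out <- out + cf[[nm]] * gridValues(grids[[nm]])
  }
  if (clip) out <- clip01(out)
  rasterGrid(out, geometry(ref))
}

#' Inverse-distance-weighted surface from sample points
#'
#' Spatializes a point-measured soil property to the basin grid with
#' inverse-distance weighting (power 2 by default); a cell whose centre
#' coincides with a sample point takes that sample's value.
#'
#' @param x,y,values sample coordinates and values.
#' @param geom a [BasinGeometry-class].
#' @param power IDW exponent (default 2).
#' @return a [RasterGrid-class].
#' @export
idwSurface <- function(x, y, values, geom, power = 2) {
  stopifnot(length(x) == length(y), length(x) == length(values),
            length(x) >= 1)
  cc <- cellCenters(geom)
  cx <- rep(cc$x, each = geom@nRows)
  cy <- rep(cc$y, times = geom@nCols)
  out <- numeric(length(cx))
  d2 <- outer(cx, x, "-")^2 + outer(cy, y, "-")^2
  hit <- d2 < .Machine$double.eps
  w <- 1 / d2^(power / 2)
  anyHit <- rowSums(hit) > 0
  out[!anyHit] <- (w[!anyHit, , drop = FALSE] %*% values) /
    rowSums(w[!anyHit, , drop = FALSE])
  if (any(anyHit))
    out[anyHit] <- apply(hit[anyHit, , drop = FALSE], 1,
                         function(h) mean(values[h]))
  rasterGrid(matrix(out, geom@nRows, geom@nCols), geom)
}
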