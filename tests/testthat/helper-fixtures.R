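# Shared small fixtures and independent oracles used across tests.

tinyGeom <- function(n = 12, seed = 1) generateGeometry(n, n, seed = seed)

constGrid <- function(value, geom) rasterGrid(value, geom)

# stack of constant layers on a tiny geometry
constStack <- function(values, geom, years = 2020,
                       months = seq_along(values), variable = "v") {
  timeSeriesStack(lapply(values, function(v) rasterGrid(v, geom)),
                  years = years, months = months, variable = variable,
                  geom = geom)
}

# independent Spearman oracle: mid-ranks computed from sorted positions,
# then the explicit Pearson formula (no call to rank()/cor() shortcuts
# shared with the implementation path)
oracleSpearman <- function(x, y) {
  midRank <- function(v) {
    sapply(v, function(vi) mean(which(sort(v) == vi)))
  }
  rx <- midRank(x); ry <- midRank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# exhaustive enumeration of the gate-stable subsets: a subset is
# "stable" when every included term has partial-F p below pRemove and
# no excluded term would enter below pEnter. Stepwise must terminate on
# one of these; when the stable subset is unique it must be that one.
oracleStableSubsets <- function(data, predictors, response = "SM",
                                pEnter = 0.05, pRemove = 0.10) {
  p <- length(predictors)
  stable <- list()
  for (mask in 0:(2^p - 1)) {
    inc <- predictors[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0]
    fit <- lm(reformulate(if (length(inc)) inc else "1", response),
              data = data)
    ok <- TRUE
    if (length(inc)) {
      d1 <- suppressWarnings(drop1(fit, test = "F"))
      pv <- d1[["Pr(>F)"]][-1]
      if (any(!is.finite(pv)) || any(pv >= pRemove)) ok <- FALSE
    }
    if (ok) {
      out <- setdiff(predictors, inc)
      if (length(out)) {
        a1 <- suppressWarnings(add1(fit, scope = reformulate(predictors),
                                    test = "F"))
        pv <- a1[["Pr(>F)"]][-1]
        if (any(is.finite(pv) & pv < pEnter)) ok <- FALSE
      }
    }
    if (ok) stable <- c(stable, list(inc))
  }
  stable
}

# exhaustive single-tree CART oracle replicating the forest's split
# rules (count-weighted Gini gain, midpoint thresholds, first-best in
# natural feature order, minLeaf) and accumulating node-fraction
# weighted gains per feature.
oracleTreeImportance <- function(x, y, minLeaf = 5) {
  x <- as.matrix(x)
  nTotal <- nrow(x)
  imp <- numeric(ncol(x))
  lev <- levels(factor(y))
  giniOf <- function(lab) {
    p <- table(factor(lab, levels = lev)) / length(lab)
    1 - sum(p^2)
  }
  grow <- function(idx) {
    n <- length(idx)
    gParent <- giniOf(y[idx])
    if (n < 2 * minLeaf || gParent <= 1e-15) return(invisible())
    bestGain <- 0; bestF <- NA; bestThr <- NA
    for (f in seq_len(ncol(x))) {
      v <- x[idx, f]
      ord <- order(v)
      vs <- v[ord]
      for (t in seq_len(n - 1)) {
        if (vs[t + 1] <= vs[t]) next
        nl <- t; nr <- n - t
        if (nl < minLeaf || nr < minLeaf) next
        thr <- (vs[t] + vs[t + 1]) / 2
        left <- idx[v <= thr]; right <- idx[v > thr]
        gain <- gParent - length(left) / n * giniOf(y[left]) -
          length(right) / n * giniOf(y[right])
        if (gain > bestGain + 1e-12 && gain > 1e-12) {
          bestGain <- gain; bestF <- f; bestThr <- thr
        }
      }
    }
    if (is.na(bestF)) return(invisible())
    imp[bestF] <<- imp[bestF] + bestGain * n / nTotal
    grow(idx[x[idx, bestF] <= bestThr])
    grow(idx[x[idx, bestF] > bestThr])
  }
  grow(seq_len(nTotal))
  imp
}
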