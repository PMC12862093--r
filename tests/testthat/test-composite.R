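test_that("KMO matches the anti-image formula and its limits", {
  # identity correlation: no shared variance -> 0 with a warning
  expect_warning(k0 <- kmo(diag(3)), "undefined")
  expect_equal(k0, 0)
  # brute-force oracle for 3 equicorrelated variables: the partial
  # correlation of i,j given k is (r - r^2) / (1 - r^2)
  r <- 0.8
  R <- matrix(r, 3, 3); diag(R) <- 1
  q <- (r - r^2) / (1 - r^2)
  oracle <- (6 * r^2) / (6 * r^2 + 6 * q^2)
  expect_equal(kmo(R), oracle, tolerance = 1e-12)
  # equicorrelated r -> 1: partials tend to r/(1+r) = 1/2, so the
  # three-variable measure tends to 1/(1 + 1/4) = 0.8
  R2 <- matrix(0.999, 3, 3); diag(R2) <- 1
  q2 <- (0.999 - 0.999^2) / (1 - 0.999^2)
  expect_equal(kmo(R2), 0.999^2 / (0.999^2 + q2^2), tolerance = 1e-9)
  # with many indicators sharing one factor the partials vanish and
  # the measure does approach 1
  R10 <- matrix(0.9, 10, 10); diag(R10) <- 1
  expect_gt(kmo(R10), 0.95)
  expect_error(kmo(matrix(1, 3, 3)), "singular")
})

test_that("Bartlett's sphericity test matches the determinant formula", {
  b0 <- bartlettSphericity(diag(4), 50)
  expect_equal(b0$chisq, 0)
  expect_equal(b0$p, 1)
  expect_equal(bartlettSphericity(diag(3), 10)$df, 3)
  R <- matrix(0.6, 3, 3); diag(R) <- 1
  b <- bartlettSphericity(R, 100)
  expect_equal(b$chisq, -(100 - 1 - 11 / 6) * log(det(R)),
               tolerance = 1e-12)
  expect_lt(b$p, 1e-10)
  expect_error(bartlettSphericity(R, 3), "exceed")
})

test_that("correlation-matrix PCA agrees with the SVD of the z-scored data", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(150), 50, 3) %*%
      matrix(rnorm(9, sd = 0.7) + diag(3), 3, 3)
    p <- indicatorPca(X)
    expect_equal(sum(p@eigenvalues), 3, tolerance = 1e-9)
    expect_equal(p@cumulativePct, cumsum(p@variancePct), tolerance = 1e-9)
    expect_equal(p@cumulativePct[3], 100, tolerance = 1e-9)
    sv <- svd(scale(X))
    expect_equal(p@eigenvalues, sv$d^2 / 49, tolerance = 1e-8)
    L <- sv$v %*% diag(sv$d / sqrt(49))
    expect_equal(abs(p@loadings), abs(L), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # varimax preserves communalities
    expect_equal(p@communalities,
                 rowSums(p@rotatedLoadings^2), tolerance = 1e-9,
                 ignore_attr = TRUE)
    # score coefficients are R^-1 times the rotated loadings
    expect_equal(p@scoreCoefficients,
                 solve(cor(X), p@rotatedLoadings), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # perfectly correlated pair: first component carries everything
  x <- rnorm(30)
  p2 <- indicatorPca(cbind(a = x, b = 2 * x + 1), nRetain = 1)
  expect_equal(p2@eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(p2@variancePct[1], 100, tolerance = 1e-9)
  expect_error(indicatorPca(matrix(rnorm(6), 2, 3)), "fewer observations")
})

test_that("communalities reproduce the published component-matrix fixtures", {
  L <- matrix(c(0.935, 0.919, 0.776, -0.228, -0.300, 0.630), 3, 2,
              dimnames = list(c("NPP", "LAI", "ARVI"), NULL))
  comm <- communalityFromLoadings(L)
  expect_equal(unname(comm), c(0.926209, 0.934561, 0.999076),
               tolerance = 1e-9)
  # printed extraction values hold to three decimals
  expect_equal(unname(round(comm, 3)), c(0.926, 0.935, 0.999))
  expect_lt(max(abs(comm - c(0.927, 0.935, 0.999))), 0.001)
})

test_that("composite weights combine score equations by rotated eigenvalue share", {
  S <- matrix(c(0.570, 0.637, -0.367, -0.130, -0.245, 1.159), 3, 2,
              dimnames = list(c("NPP", "LAI", "ARVI"), NULL))
  w <- compositeWeights(S, rotatedSS = c(1.778, 1.083))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_lt(max(abs(w - c(NPP = 0.372, LAI = 0.370, ARVI = 0.258))), 0.005)
  expect_equal(unname(w), c(0.3725233, 0.3702100, 0.2572667),
               tolerance = 1e-6)
  # single component, single indicator
  expect_equal(unname(compositeWeights(matrix(0.7, 1, 1), rotatedSS = 2)), 1)
  # two identical indicators share the weight equally
  w2 <- compositeWeights(matrix(c(0.5, 0.5), 2, 1), rotatedSS = 1.5)
  expect_equal(unname(w2), c(0.5, 0.5))
  expect_warning(compositeWeights(matrix(c(-0.2, 0.8), 2, 1),
                                  rotatedSS = 1), "negative")
})

test_that("index selection gates on correlation, Bartlett and KMO", {
  set.seed(21)
  n <- 200
  f <- rnorm(n)
  npp <- f + rnorm(n, 0, 0.4)
  lai <- f + rnorm(n, 0, 0.4)
  good <- f + rnorm(n, 0, 0.3)          # shares the latent factor
  weak <- 0.2 * f + rnorm(n, 0, 1)      # mostly noise
  sel <- selectBestIndex(list(good = good, weak = weak), npp, lai)
  expect_equal(sel$index, "good")
  expect_true(sel$passedGates)
  # candidate identical to LAI passes the correlation gate trivially
  sel2 <- selectBestIndex(list(cand = lai, weak = weak), npp, lai)
  expect_true(sel2$table$passed[sel2$table$candidate == "cand"])
  # planted-latent candidate wins across seeds
  hits <- sapply(1:10, function(s) {
    set.seed(s + 100)
    f <- rnorm(n)
    npp <- f + rnorm(n, 0, 0.4); lai <- f + rnorm(n, 0, 0.4)
    cands <- list(arvi = f + rnorm(n, 0, 0.3),
                  other1 = 0.3 * f + rnorm(n),
                  other2 = 0.3 * f + rnorm(n))
    selectBestIndex(cands, npp, lai)$index == "arvi"
  })
  expect_gte(mean(hits), 0.9)
  # nothing passes: flagged, best KMO still returned
  set.seed(5)
  pure <- replicate(2, rnorm(n), simplify = FALSE)
  expect_message(
    sel3 <- selectBestIndex(list(a = pure[[1]], b = pure[[2]]),
                            rnorm(n), rnorm(n)), "no candidate")
  expect_false(sel3$passedGates)
})

test_that("the VEG raster is a weighted sum of rescaled indicators in [0, 1]", {
  g <- tinyGeom()
  w <- c(NPP = 0.372, LAI = 0.370, ARVI = 0.258)
  w <- w / sum(w)
  set.seed(7)
  grids <- list(NPP = rasterGrid(matrix(runif(144, 10, 100), 12), g),
                LAI = rasterGrid(matrix(runif(144, 0, 5), 12), g),
                ARVI = rasterGrid(matrix(runif(144, -0.2, 0.9), 12), g))
  out <- vegRaster(w, grids)
  v <- gridValues(out)[basinMask(g)]
  expect_true(all(v >= 0 & v <= 1))
  # weights (1, 0, 0): output equals the rescaled first indicator
  out1 <- vegRaster(c(NPP = 1, LAI = 0, ARVI = 0), grids)
  expect_equal(gridValues(out1), gridValues(minMaxRescale(grids$NPP)))
  # constant indicators give a constant composite
  cg <- list(NPP = rasterGrid(5, g), LAI = rasterGrid(2, g),
             ARVI = rasterGrid(0.3, g))
  expect_equal(unique(gridValues(vegRaster(w, cg))[basinMask(g)]), 0.5)
  expect_error(vegRaster(w, grids[1:2]), "missing indicator")
})

test_that("the full PCA-to-weights path approximates the reference weights", {
  # correlation structure implied by the reference two-component
  # loading matrix (rank-2 reconstruction with unit diagonal); the
  # truncation to two components shifts the spectrum slightly, so the
  # printed weights are recovered approximately, not exactly
  L <- matrix(c(0.935, 0.919, 0.776, -0.228, -0.300, 0.630), 3, 2,
              dimnames = list(c("NPP", "LAI", "ARVI"), NULL))
  R <- L %*% t(L); diag(R) <- 1
  p <- indicatorPca(R, correlation = TRUE)
  expect_equal(p@nRetained, 2L)
  w <- compositeWeights(p)
  expect_equal(unname(w), c(0.3759, 0.3732, 0.2509), tolerance = 1e-3)
  expect_lt(max(abs(w - c(NPP = 0.372, LAI = 0.370, ARVI = 0.258))), 0.01)
  expect_gt(min(w[c("NPP", "LAI")]), w[["ARVI"]])
})
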