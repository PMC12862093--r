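test_that("Gini impurity and split gain match their formulas", {
  expect_equal(giniImpurity(c(10, 0)), 0)
  expect_equal(giniImpurity(c(5, 5)), 0.5)
  expect_equal(giniImpurity(rep(4, 5)), 0.8)
  expect_error(giniImpurity(c(0, 0)), "empty")
  expect_error(giniImpurity(c(-1, 3)), "negative")
  expect_equal(giniGain(c(10, 10), c(10, 0), c(0, 10)), 0.5)
  expect_equal(giniGain(c(10, 10), c(5, 5), c(5, 5)), 0)
  expect_error(giniGain(c(10, 10), c(5, 5), c(4, 5)), "equal parent")
  set.seed(17)
  for (i in 1:20) {
    parent <- rmultinom(1, 40, c(0.3, 0.4, 0.3))[, 1]
    left <- sapply(parent, function(k) rbinom(1, k, 0.5))
    expect_gte(giniGain(parent, left, parent - left), -1e-12)
  }
})

test_that("forest importance is normalized, seeded and finds planted signal", {
  set.seed(18)
  n <- 300
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- factor(ifelse(x$a > 0, "pos", "neg"))
  f <- fitGiniForest(x, y, nTrees = 100, seed = 3)
  expect_equal(sum(f$importance$share), 1, tolerance = 1e-12)
  expect_true(all(f$importance$share >= 0))
  expect_equal(f$importance$feature[f$importance$rank == 1], "a")
  expect_gt(f$importance$share[f$importance$feature == "a"], 0.5)
  expect_identical(f$importance,
                   fitGiniForest(x, y, nTrees = 100, seed = 3)$importance)
  expect_gt(mean(predict(f, x) == y), 0.95)
  expect_error(fitGiniForest(x, factor(rep("one", n))), "single-class")
  expect_error(fitGiniForest(x[1:30, ], y[1:30]), "at least 50")
})

test_that("single-tree importance equals the exhaustive CART oracle", {
  for (s in 1:3) {
    set.seed(s + 30)
    n <- 80
    x <- cbind(f1 = rnorm(n), f2 = rnorm(n))
    y <- factor(ifelse(x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.8) > 0,
                       "hi", "lo"))
    f <- fitGiniForest(x, y, nTrees = 1, mtry = 2, bootstrap = FALSE,
                       seed = s)
    oracle <- oracleTreeImportance(x, y, minLeaf = 5)
    expect_equal(f$importance$giniDecrease, oracle, tolerance = 1e-10)
  }
})

test_that("forest ranking agrees with an independent random forest", {
  skip_if_not_installed("randomForest")
  set.seed(19)
  n <- 400
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  y <- factor(ifelse(x$a + 0.4 * x$b + rnorm(n, 0, 0.5) > 0, "hi", "lo"))
  f <- fitGiniForest(x, y, nTrees = 200, seed = 1)
  rf <- randomForest::randomForest(x, y, ntree = 200)
  ours <- f$importance$share
  theirs <- rf$importance[, "MeanDecreaseGini"] /
    sum(rf$importance[, "MeanDecreaseGini"])
  expect_equal(order(-ours)[1:2], order(-theirs)[1:2])
  expect_lt(max(abs(ours - theirs)), 0.1)
})

test_that("regression mode uses variance impurity on continuous targets", {
  set.seed(20)
  n <- 200
  x <- data.frame(a = runif(n), b = runif(n))
  y <- 2 * x$a + rnorm(n, 0, 0.1)
  f <- fitGiniForest(x, y, nTrees = 100, seed = 2)
  expect_equal(f$mode, "regression")
  expect_equal(f$importance$feature[f$importance$rank == 1], "a")
  pred <- predict(f, x)
  expect_gt(cor(pred, y), 0.9)
})

test_that("driver importance classifies D, subsamples and reports shares", {
  g <- generateGeometry(32, 32, seed = 5)
  ds <- generateDriverStack(g, seed = 5)
  f <- driverImportance(ds$drivers, ds$latent, nTrees = 100, seed = 5,
                        maxPixels = 400)
  expect_equal(sum(f$importance$share), 1, tolerance = 1e-12)
  expect_setequal(f$importance$feature, driverNames())
  # degenerate single-class target is refused
  expect_error(driverImportance(ds$drivers, rasterGrid(0.5, g),
                                nTrees = 10), "degenerate")
})

test_that("ranking consistency across depths is summarized by Kendall's tau", {
  a <- stats::setNames((8:1) / sum(1:8), driverNames())
  b <- a
  rc <- rankConsistency(list(d1 = a, d2 = b))
  expect_true(rc$consistent)
  expect_equal(unname(rc$tau[1, 2]), 1)
  rev <- stats::setNames(rev(unname(a)), names(a))
  rc2 <- rankConsistency(list(d1 = a, d2 = rev))
  expect_equal(unname(rc2$tau[1, 2]), -1)
  expect_false(rc2$consistent)
  expect_error(rankConsistency(list(a)), "at least two")
  bad <- stats::setNames(a, c(driverNames()[-1], "other"))
  expect_error(rankConsistency(list(a, bad)), "mismatched")
  # common planted truth across three depth runs: rankings stay
  # strongly concordant and the two lead drivers are always on top
  # (full tau = 1 requires the near-tied tail drivers to sort
  # identically, which finite forests do not guarantee)
  res <- sapply(1:5, function(s) {
    g <- generateGeometry(32, 32, seed = s + 60)
    ds <- generateDriverStack(g, seed = s + 60)
    reps <- lapply(1:3, function(d)
      driverImportance(ds$drivers, ds$latent, nTrees = 300,
                       seed = s * 10 + d))
    c(tau = min(rankConsistency(reps)$tau),
      top2 = all(vapply(reps, function(r)
        setequal(r$importance$feature[r$importance$rank <= 2],
                 c("LST", "PET")), logical(1))))
  })
  expect_true(all(res["tau", ] >= 0.7))
  expect_true(all(res["top2", ] == 1))
})
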