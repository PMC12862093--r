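test_that("predictor screening ranks by |r| and gates on the t-test p-value", {
  set.seed(3)
  n <- 60
  d <- data.frame(site = 1:n, depth = "0-10", SM = runif(n))
  d$copy <- d$SM
  d$anti <- -d$SM
  d$flat <- 1
  d$noise <- rnorm(n)
  expect_message(scr <- screenPredictors(d, "0-10",
                                         candidates = c("copy", "anti",
                                                        "flat", "noise")),
                 "constant")
  expect_false("flat" %in% scr$predictor)
  expect_true(scr$retained[scr$predictor == "copy"])
  expect_true(scr$retained[scr$predictor == "anti"])   # two-sided
  expect_equal(scr$r[scr$predictor == "copy"], 1)
  expect_equal(scr$predictor[1:2] %in% c("copy", "anti"), c(TRUE, TRUE))
  # p-value agrees with cor.test
  ct <- cor.test(d$noise, d$SM)
  expect_equal(scr$p[scr$predictor == "noise"], unname(ct$p.value),
               tolerance = 1e-12)
})

test_that("site splitting gives floor-based ratios, disjoint and seeded", {
  tab <- generateSoilSamples(170, seed = 1)
  sp <- splitSamples(tab, 4, seed = 9)
  expect_equal(length(unique(sp$train$site)), 136)
  expect_equal(length(unique(sp$valid$site)), 34)
  expect_length(intersect(sp$train$site, sp$valid$site), 0)
  expect_identical(sp, splitSamples(tab, 4, seed = 9))
  tab20 <- generateSoilSamples(20, seed = 1)
  sp20 <- splitSamples(tab20, 4, seed = 1)
  expect_equal(length(unique(sp20$train$site)), 16)
  expect_equal(length(unique(sp20$valid$site)), 4)
})

test_that("stepwise recovers the zero-noise truth and guards the null case", {
  tab <- generateSoilSamples(170, smTruthConfig(noiseSd = 0), seed = 1)
  sp <- splitSamples(tab, 4, seed = 2)
  tr <- sp$train[sp$train$depth == "0-10", ]
  scr <- screenPredictors(tab, "0-10")
  m <- fitSMLR(tr, scr$predictor[scr$retained], depth = "0-10")
  expect_setequal(names(m@coefficients), c("P_cap", "BD"))
  expect_equal(m@intercept, -0.105, tolerance = 1e-6)
  expect_equal(unname(m@coefficients["P_cap"]), 0.013, tolerance = 1e-6)
  expect_equal(unname(m@coefficients["BD"]), 0.084, tolerance = 1e-6)
  # pure-noise candidates: intercept-only with a message (single seed)
  set.seed(4)
  d <- data.frame(SM = rnorm(100), z1 = rnorm(100), z2 = rnorm(100))
  expect_message(m0 <- fitSMLR(d, c("z1", "z2")), "intercept-only")
  expect_length(m0@coefficients, 0)
  expect_error(fitSMLR(d, c("z1", "z2"), pEnter = 0.2, pRemove = 0.1),
               "pEnter")
})

test_that("stepwise false entry of a null candidate occurs at about the entry rate", {
  hits <- sapply(1:60, function(s) {
    tab <- generateSoilSamples(60, smTruthConfig(noiseSd = 0.005), seed = s)
    tr <- tab[tab$depth == "0-10", ]
    m <- fitSMLR(tr, c("P_cap", "BD", "TN"), depth = "0-10")
    c(truthIn = all(c("P_cap", "BD") %in% names(m@coefficients)),
      extraIn = "TN" %in% names(m@coefficients))
  })
  expect_equal(mean(hits["truthIn", ]), 1)   # truth always recovered
  pEnter <- 0.05
  se <- sqrt(pEnter * (1 - pEnter) / 60)
  expect_lt(abs(mean(hits["extraIn", ]) - pEnter), 3 * se)
})

test_that("stepwise terminates on a gate-stable subset found by exhaustive search", {
  for (s in 1:5) {
    tab <- generateSoilSamples(60, smTruthConfig(noiseSd = 0.01),
                               seed = s + 40)
    tr <- tab[tab$depth == "0-10", ]
    pool <- c("P_cap", "BD", "TN", "TP", "AK", "P_non")
    m <- fitSMLR(tr, pool, depth = "0-10")
    stable <- oracleStableSubsets(tr, pool)
    hit <- vapply(stable, setequal, logical(1), y = names(m@coefficients))
    expect_true(any(hit))
    # when the gates admit a single stable subset, stepwise must find it
    if (length(stable) == 1L)
      expect_setequal(names(m@coefficients), stable[[1]])
  }
  # strong planted signal with a unique stable subset: exact agreement
  tab <- generateSoilSamples(120, smTruthConfig(noiseSd = 0.002), seed = 77)
  tr <- tab[tab$depth == "0-10", ]
  m <- fitSMLR(tr, c("P_cap", "BD", "TN", "TP"), depth = "0-10")
  stable <- oracleStableSubsets(tr, c("P_cap", "BD", "TN", "TP"))
  expect_true(any(vapply(stable, setequal, logical(1),
                         y = names(m@coefficients))))
  expect_true(all(c("P_cap", "BD") %in% names(m@coefficients)))
})

test_that("ridge reduces to least squares at zero penalty and shrinks correctly", {
  tab <- generateSoilSamples(80, smTruthConfig(noiseSd = 0.01), seed = 6)
  tr <- tab[tab$depth == "0-10", ]
  mr <- fitRidge(tr, c("P_cap", "BD", "TN"), penaltyGrid = 0)
  ols <- lm(SM ~ P_cap + BD + TN, tr)
  expect_equal(mr@intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_equal(unname(mr@coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-8)
  # independent cross-check against MASS::lm.ridge at zero penalty
  lr <- MASS::lm.ridge(SM ~ P_cap + BD + TN, tr, lambda = 0)
  expect_equal(unname(mr@coefficients), unname(coef(lr)[-1]),
               tolerance = 1e-6)
  # penalty -> infinity: slopes vanish, intercept -> mean(SM)
  mbig <- fitRidge(tr, c("P_cap", "BD"), penaltyGrid = 1e12)
  expect_equal(unname(mbig@coefficients), c(0, 0), tolerance = 1e-6)
  expect_equal(mbig@intercept, mean(tr$SM), tolerance = 1e-6)
  # duplicated predictor: L2 symmetry puts equal weight on the pair
  tr$P_cap2 <- tr$P_cap
  mdup <- fitRidge(tr, c("P_cap", "P_cap2"), penaltyGrid = 1)
  expect_equal(unname(mdup@coefficients["P_cap"]),
               unname(mdup@coefficients["P_cap2"]), tolerance = 1e-10)
})

test_that("PLSR reproduces least squares at full rank and finds one latent factor", {
  tab <- generateSoilSamples(80, smTruthConfig(noiseSd = 0.01), seed = 8)
  tr <- tab[tab$depth == "0-10", ]
  mp <- fitPLSR(tr, c("P_cap", "BD", "TN"), maxComponents = 3)
  ols <- lm(SM ~ P_cap + BD + TN, tr)
  pred <- predict(mp, tr)
  expect_equal(pred, unname(fitted(ols)), tolerance = 1e-8)
  expect_error(fitPLSR(tr, c("P_cap", "BD"), maxComponents = 0), ">= 1")
  # single predictor equals simple regression
  m1 <- fitPLSR(tr, "P_cap", maxComponents = 1)
  sl <- lm(SM ~ P_cap, tr)
  expect_equal(unname(m1@coefficients), unname(coef(sl)[2]),
               tolerance = 1e-8)
  # one latent factor: cross-validation selects a single component
  picks <- sapply(1:5, function(s) {
    set.seed(s)
    n <- 100; f <- rnorm(n)
    X <- outer(f, c(1, 0.8, 0.6, 0.9)) +
      matrix(rnorm(n * 4, 0, 0.3), n, 4)
    d <- data.frame(X, SM = 0.4 + 0.1 * f + rnorm(n, 0, 0.02))
    names(d)[1:4] <- paste0("v", 1:4)
    fitPLSR(d, paste0("v", 1:4), seed = s)@hyper$nComponents
  })
  expect_gte(mean(picks == 1), 0.8)
})

test_that("validation metrics match their definitions", {
  m <- regressionMetrics(c(0.2, 0.4), c(0.3, 0.3))
  expect_equal(unname(m["RMSE"]), 0.1, tolerance = 1e-9)
  expect_equal(unname(m["MAE"]), 0.1, tolerance = 1e-9)
  expect_equal(unname(m["MAPE"]), (50 + 25) / 2, tolerance = 1e-9)
  expect_equal(unname(m["R2"]), 1 - 0.02 / 0.02, tolerance = 1e-9)
  x <- runif(20, 0.2, 0.8)
  perfect <- regressionMetrics(x, x)
  expect_equal(unname(perfect), c(1, 0, 0, 0))
  atMean <- regressionMetrics(x, rep(mean(x), 20))
  expect_equal(unname(atMean["R2"]), 0)
  expect_warning(regressionMetrics(c(0, 0.5), c(0.1, 0.4)), "MAPE")
  # RMSE >= MAE on arbitrary errors
  set.seed(10)
  for (i in 1:10) {
    mm <- regressionMetrics(runif(30, 0.1, 1), runif(30, 0.1, 1))
    expect_gte(mm[["RMSE"]], mm[["MAE"]])
  }
})

test_that("model selection applies the error gates then the R2 argmax", {
  rep1 <- data.frame(method = c("SMLR", "Ridge"), depth = "0-10",
                     R2 = c(0.97, 0.96), RMSE = c(0.03, 0.02),
                     MAE = c(0.01, 0.01), MAPE = c(10, 10), p = 0,
                     nValid = 34)
  sel <- selectModel(rep1)
  expect_equal(sel$method, "SMLR")          # larger R2 among passers
  expect_true(sel$passedGates)
  rep2 <- rep1; rep2$RMSE <- c(0.06, 0.02); rep2$R2 <- c(0.99, 0.90)
  expect_equal(selectModel(rep2)$method, "Ridge")  # RMSE gate excludes SMLR
  rep3 <- rep1; rep3$MAE <- c(0.5, 0.4)
  expect_message(sel3 <- selectModel(rep3), "no candidate met")
  expect_false(sel3$passedGates)
  expect_equal(sel3$method, "Ridge")        # min RMSE fallback
  # equal R2 tie prefers the earlier method order
  rep4 <- rep1; rep4$R2 <- c(0.95, 0.95)
  expect_equal(selectModel(rep4)$method, "SMLR")
})

test_that("raster prediction evaluates the linear model cellwise with clipping", {
  g <- tinyGeom()
  m1 <- new("FittedModel", method = "SMLR", depth = "0-10",
            intercept = -0.105, coefficients = c(P_cap = 0.013, BD = 0.084),
            hyper = list(), screened = c("P_cap", "BD"))
  out <- predictRaster(m1, list(P_cap = rasterGrid(50, g),
                                BD = rasterGrid(1.3, g)))
  expect_equal(unique(gridValues(out)[basinMask(g)]), 0.6542,
               tolerance = 1e-9)
  m3 <- new("FittedModel", method = "SMLR", depth = "20-30",
            intercept = -0.115, coefficients = c(P_cap = 0.013, BD = 0.091),
            hyper = list(), screened = c("P_cap", "BD"))
  out3 <- predictRaster(m3, list(P_cap = rasterGrid(40, g),
                                 BD = rasterGrid(1.2, g)))
  expect_equal(unique(gridValues(out3)[basinMask(g)]), 0.5142,
               tolerance = 1e-9)
  expect_error(predictRaster(m1, list(P_cap = rasterGrid(50, g))),
               "missing predictor")
  # nodata in any predictor propagates; clipping bounds the output
  pv <- gridValues(rasterGrid(50, g)); pv[4, 4] <- NA
  out4 <- predictRaster(m1, list(P_cap = rasterGrid(pv, g),
                                 BD = rasterGrid(1.3, g)))
  expect_true(is.na(gridValues(out4)[4, 4]))
  big <- predictRaster(m1, list(P_cap = rasterGrid(100, g),
                                BD = rasterGrid(1.6, g)))
  expect_equal(unique(gridValues(big)[basinMask(g)]), 1)
})

test_that("IDW surfaces honour exact hits and inverse-square weighting", {
  g <- generateGeometry(12, 12, cellSize = 1, origin = c(0, 0), seed = 1)
  ccx <- 0.5 + 0:11; ccy <- rev(0.5 + 0:11)
  s <- idwSurface(x = c(ccx[2], ccx[9]), y = c(ccy[2], ccy[9]),
                  values = c(1, 3), geom = g)
  v <- gridValues(s)
  expect_equal(v[2, 2], 1)                  # exact sample hit
  expect_equal(v[9, 9], 3)
  mid <- v[6, 6]
  if (!is.na(mid)) expect_true(mid > 1 && mid < 3)
})
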