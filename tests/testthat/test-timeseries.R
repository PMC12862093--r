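test_that("outlier flagging applies the floor and spike rules", {
  g <- tinyGeom()
  expect_error(flagOutliers(constStack(list(0.1, 0.2), g)), "at least 3")
  m <- basinMask(g)
  fl <- flagOutliers(constStack(list(0.5, -0.2, 0.5), g), lowThreshold = 0)
  expect_true(all(fl[, , 2][m]))
  expect_false(any(fl[, , c(1, 3)][rep(m, 2)]))
  # constant series: nothing flagged
  fl0 <- flagOutliers(constStack(list(0.3, 0.3, 0.3), g), lowThreshold = 0)
  expect_false(any(fl0))
  # spike vs equal neighbours: any deviation exceeds spikeFactor * 0
  fl2 <- flagOutliers(constStack(list(0.4, 0.9, 0.4), g), 0, spikeFactor = 2)
  expect_true(all(fl2[, , 2][m]))
  # deviation within spikeFactor * neighbour range: not flagged
  fl3 <- flagOutliers(constStack(list(0.2, 0.7, 0.6), g), 0, spikeFactor = 2)
  expect_false(any(fl3[, , 2][m]))
})

test_that("linear gap-fill interpolates interior gaps and extends boundaries", {
  g <- tinyGeom(); m <- basinMask(g)
  st <- constStack(list(0.2, 9, 0.6), g)
  fl <- array(FALSE, dim = c(12, 12, 3)); fl[, , 2] <- TRUE
  out <- linearGapfill(st, fl)
  expect_equal(unique(out@layers[[2]][m]), 0.4)
  expect_equal(out@layers[[1]], st@layers[[1]])   # unflagged untouched
  st2 <- constStack(list(9, 0.3, 0.5), g)
  fl2 <- array(FALSE, dim = c(12, 12, 3)); fl2[, , 1] <- TRUE
  expect_equal(unique(linearGapfill(st2, fl2)@layers[[1]][m]), 0.3)
  st3 <- constStack(list(0.1, 9, 9, 0.7), g)
  fl3 <- array(FALSE, dim = c(12, 12, 4)); fl3[, , 2:3] <- TRUE
  out3 <- linearGapfill(st3, fl3)
  expect_equal(unique(out3@layers[[2]][m]), 0.3)
  expect_equal(unique(out3@layers[[3]][m]), 0.5)
  # a cell with < 2 valid points becomes nodata, with a message
  st4 <- constStack(list(0.1, 0.2, 0.3), g)
  fl4 <- array(FALSE, dim = c(12, 12, 3)); fl4[, , 2:3] <- TRUE
  expect_message(out4 <- linearGapfill(st4, fl4), "< 2 valid")
  expect_true(all(is.na(out4@layers[[2]][m])))
})

test_that("maximum-value composites take cellwise maxima over valid cells", {
  g <- tinyGeom(); m <- basinMask(g)
  st <- constStack(list(0.2, 0.5, 0.3), g)
  expect_equal(unique(gridValues(mvcComposite(st))[m]), 0.5)
  expect_error(mvcComposite(st, layers = integer(0)), "empty")
  # single-layer window is the identity
  expect_equal(gridValues(mvcComposite(st, layers = 2)),
               rasterGrid(st@layers[[2]], g)@values)
  # all-nodata cell stays nodata; composite dominates every input
  v <- st@layers[[1]]; v[m][1] <- NA
  stNA <- timeSeriesStack(list(v, v, v), 2020, 1:3, geom = g)
  expect_true(is.na(gridValues(mvcComposite(stNA))[m][1]))
  set.seed(2)
  rnd <- constStack(lapply(1:4, function(i) runif(1)), g)
  comp <- gridValues(mvcComposite(rnd))
  for (l in rnd@layers) expect_true(all(comp[m] >= l[m]))
})

test_that("seasonal and annual aggregation follow the season calendar", {
  g <- tinyGeom(); m <- basinMask(g)
  # 14 months: Nov(2019), Dec(2019), Jan..Dec(2020), values i/100
  st <- timeSeriesStack(lapply(1:14, function(i) rasterGrid(i / 100, g)),
                        years = c(2019, 2019, rep(2020, 12)),
                        months = c(11, 12, 1:12), variable = "v", geom = g)
  expect_equal(unique(gridValues(seasonalAggregate(st, 2020, "summer"))[m]),
               mean(c(8, 9, 10) / 100))
  # winter of 2020 = Dec 2019 + Jan, Feb 2020
  expect_equal(unique(gridValues(seasonalAggregate(st, 2020, "winter"))[m]),
               mean(c(2, 3, 4) / 100))
  expect_equal(unique(gridValues(annualMean(st, 2020))[m]),
               mean((3:14) / 100))
  expect_error(seasonalAggregate(st, 2019, "summer"), "missing month")
  expect_error(annualMean(st, 2019), "missing month")
  # constant field: any seasonal mean equals the constant
  stc <- constStack(rep(list(0.3), 12), g, years = 2021, months = 1:12)
  for (s in c("spring", "summer", "autumn"))
    expect_equal(unique(gridValues(seasonalAggregate(stc, 2021, s))[m]), 0.3)
})

test_that("stack construction validates time ordering and geometry", {
  g <- tinyGeom()
  expect_error(new("TimeSeriesStack", variable = "v",
                   times = data.frame(year = c(2020L, 2020L),
                                      month = c(5L, 4L)),
                   layers = list(matrix(0, 12, 12), matrix(0, 12, 12)),
                   geometry = g), "strictly increasing")
  expect_error(new("TimeSeriesStack", variable = "v",
                   times = data.frame(year = 2020L, month = 1L),
                   layers = list(matrix(0, 6, 6)), geometry = g),
               "match the geometry")
})
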