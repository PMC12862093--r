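#' Run the full synthetic-basin coupling analysis
#'
#' Orchestrates every stage on generated data: basin geometry; soil
#' samples and per-depth inversion (predictor screening, 4:1 site
#' split, SMLR/Ridge/PLSR fits, error-gated model selection, IDW
#' spatialization and raster prediction); monthly band QC (outlier
#' flagging, linear gap-fill, maximum-value compositing) and the
#' candidate-index / NPP / LAI composite-vegetation construction (KMO,
#' Bartlett, PCA, weight normalization, VEG raster); per-pixel Spearman
#' correlation of the planted coupled SM/VEG annual series; coupling
#' coordination mapping with five-level classification; and
#' Gini-forest driver-importance ranking against the generator's
#' planted coordination field.
#'
#' The run is deterministic given \code{config$seed}. When
#' \code{outDir} is given, every intermediate raster (.asc), table
#' (.csv) and the final summary (summary.json) are written there, and
#' each threshold applied is echoed in the summary.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory.
#' @param verbose print stage progress (default TRUE).
#' @return a list summarizing every stage (invisible when writing).
#' @export
runAll <- function(config = pipelineConfig(), outDir = NULL,
                   verbose = TRUE) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  writeOut <- !is.null(outDir)
  if (writeOut && !dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stageFail <- function(stage, e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)

  ## stage: simulate -------------------------------------------------
  say("stage simulate: %dx%d basin, %d sites", config$nRows,
      config$nCols, config$nSites)
  sim <- tryCatch({
    geom <- generateGeometry(config$nRows, config$nCols, config$cellSize,
                             seed = config$seed)
    truth <- smTruthConfig(noiseSd = config$noiseSd,
                           gradientStrength = config$gradientStrength)
    samples <- generateSoilSamples(config$nSites, truth, geom,
                                   seed = config$seed)
    list(geom = geom, truth = truth, samples = samples)
  }, error = function(e) stageFail("simulate", e))
  if (writeOut)
    write.csv(sim$samples, file.path(outDir, "samples.csv"),
              row.names = FALSE)

  ## stage: invert ---------------------------------------------------
  say("stage invert: per-depth screening, fitting, selection")
  inversion <- tryCatch(lapply(depthLayers(), function(dp) {
    scr <- screenPredictors(sim$samples, dp, alpha = config$alpha)
    pool <- scr$predictor[scr$retained]
    if (length(pool) < 2) pool <- head(scr$predictor, 2)
    sp <- splitSamples(sim$samples, ratio = config$splitRatio,
                       seed = config$seed)
    tr <- sp$train[sp$train$depth == dp, ]
    va <- sp$valid[sp$valid$depth == dp, ]
    models <- list(
      SMLR = fitSMLR(tr, pool, depth = dp),
      Ridge = fitRidge(tr, pool, depth = dp, seed = config$seed),
      PLSR = fitPLSR(tr, pool, depth = dp, seed = config$seed))
    reports <- do.call(rbind, lapply(models, evaluateModel, valid = va))
    sel <- selectModel(reports, config$rmseMax, config$maeMax,
                       config$mapeMax)
    best <- models[[sel$method]]
    surf <- lapply(stats::setNames(nm = names(best@coefficients)),
                   function(nm) {
                     d1 <- sim$samples[sim$samples$depth == dp, ]
                     idwSurface(d1$x, d1$y, d1[[nm]], sim$geom)
                   })
    smMap <- predictRaster(best, surf)
    list(depth = dp, screening = scr, reports = reports, select = sel,
         model = best, smMap = smMap)
  }), error = function(e) stageFail("invert", e))
  names(inversion) <- depthLayers()
  if (writeOut) for (dp in depthLayers()) {
    writeAsciiGrid(inversion[[dp]]$smMap,
                   file.path(outDir, sprintf("sm_%s.asc", dp)))
    write.csv(inversion[[dp]]$reports,
              file.path(outDir, sprintf("metrics_%s.csv", dp)),
              row.names = FALSE)
  }

  ## stage: composite (band QC + MVC demo on NDVI) -------------------
  say("stage composite: band QC and monthly compositing")
  lastYear <- max(config$years)
  tsQc <- tryCatch({
    bands <- lapply(1:12, function(m)
      generateBandStack(sim$geom, m, seed = config$seed))
    ndviStack <- timeSeriesStack(
      lapply(bands, function(b) ndvi(b$B8, b$B4)),
      years = lastYear, months = 1:12, variable = "NDVI",
      geom = sim$geom)
    flags <- flagOutliers(ndviStack, lowThreshold = -0.2, spikeFactor = 2)
    filled <- linearGapfill(ndviStack, flags)
    list(bands = bands, ndvi = filled,
         summerMax = mvcComposite(filled, layers = 6:8),
         annual = annualMean(filled, lastYear))
  }, error = function(e) stageFail("composite", e))
  if (writeOut)
    writeAsciiGrid(tsQc$annual, file.path(outDir, "ndvi_annual.asc"))

  ## stage: veg ------------------------------------------------------
  say("stage veg: candidate screening, PCA, composite index")
  veg <- tryCatch({
    npp <- generateProductSeries(sim$geom, "NPP", years = lastYear,
                                 seed = config$seed)
    lai <- generateProductSeries(sim$geom, "LAI", years = lastYear,
                                 seed = config$seed + 1)
    nppMean <- annualMean(npp, lastYear)
    laiMean <- annualMean(lai, lastYear)
    mask <- basinMask(sim$geom)
    annualIndex <- function(ix) {
      grids <- lapply(1:12, function(m) {
        b <- tsQc$bands[[m]]
        vegIndex(ix, nir = b$B8, red = b$B4, blue = b$B2, green = b$B3)
      })
      st <- timeSeriesStack(grids, years = lastYear, months = 1:12,
                            variable = ix, geom = sim$geom)
      annualMean(st, lastYear)
    }
    idxNames <- c("ndvi", "evi", "savi", "dvi", "rvi", "arvi", "gndvi")
    idxGrids <- lapply(stats::setNames(nm = idxNames), annualIndex)
    cand <- lapply(idxGrids, function(g) gridValues(g)[mask])
    sel <- selectBestIndex(cand, gridValues(nppMean)[mask],
                           gridValues(laiMean)[mask],
                           corGate = config$corGate,
                           kmoGate = config$kmoGate, alpha = config$alpha)
    M <- cbind(NPP = gridValues(nppMean)[mask],
               LAI = gridValues(laiMean)[mask],
               IDX = cand[[sel$index]])
    colnames(M)[3] <- toupper(sel$index)
    pca <- indicatorPca(M)
    w <- compositeWeights(pca)
    vegGrid <- vegRaster(w, stats::setNames(
      list(nppMean, laiMean, idxGrids[[sel$index]]), names(w)))
    bart <- bartlettSphericity(cor(M), nrow(M))
    list(select = sel, pca = pca, weights = w, grid = vegGrid,
         kmo = kmo(cor(M)), bartlett = bart)
  }, error = function(e) stageFail("veg", e))
  if (writeOut) {
    writeAsciiGrid(veg$grid, file.path(outDir, "veg.asc"))
    write.csv(veg$select$table, file.path(outDir, "veg_candidates.csv"),
              row.names = FALSE)
  }

  ## stage: correlate ------------------------------------------------
  say("stage correlate: per-pixel Spearman of the coupled annual series")
  corr <- tryCatch({
    cs <- generateCoupledStacks(sim$geom, nYears = length(config$years),
                                startYear = min(config$years),
                                seed = config$seed)
    maps <- correlateStacks(cs$sm, cs$veg, alpha = config$alpha)
    list(stacks = cs, maps = maps, proportions = areaProportions(maps))
  }, error = function(e) stageFail("correlate", e))
  if (writeOut) {
    writeAsciiGrid(rasterGrid(corr$maps@rho, sim$geom),
                   file.path(outDir, "spearman_rho.asc"))
    writeAsciiGrid(rasterGrid(corr$maps@p, sim$geom),
                   file.path(outDir, "spearman_p.asc"))
  }

  ## stage: couple ---------------------------------------------------
  say("stage couple: coupling coordination mapping")
  coup <- tryCatch({
    smMeanGrid <- rasterGrid(apply(stackArray(corr$stacks$sm), c(1, 2),
                                   mean), sim$geom)
    vegMeanGrid <- rasterGrid(apply(stackArray(corr$stacks$veg), c(1, 2),
                                    mean), sim$geom)
    maps <- couplingMaps(vegMeanGrid, smMeanGrid, alpha = config$ccdAlpha,
                         form = config$ccdForm)
    list(maps = maps, proportions = classAreaProportions(maps))
  }, error = function(e) stageFail("couple", e))
  if (writeOut) {
    writeAsciiGrid(rasterGrid(coup$maps@dGrid, sim$geom),
                   file.path(outDir, "ccd_d.asc"))
    writeAsciiGrid(rasterGrid(coup$maps@classGrid + 0, sim$geom),
                   file.path(outDir, "ccd_class.asc"))
  }

  ## stage: importance -----------------------------------------------
  say("stage importance: Gini-forest driver ranking")
  imp <- tryCatch({
    ds <- generateDriverStack(sim$geom, seed = config$seed)
    forest <- driverImportance(ds$drivers, ds$latent,
                               nTrees = config$nTrees, mtry = config$mtry,
                               minLeaf = config$minLeaf,
                               maxPixels = config$maxPixels,
                               seed = config$seed)
    list(drivers = ds, forest = forest,
         importance = forest$importance[order(forest$importance$rank), ])
  }, error = function(e) stageFail("importance", e))
  if (writeOut)
    write.csv(imp$importance, file.path(outDir, "importance.csv"),
              row.names = FALSE)

  summary <- list(
    seed = config$seed,
    thresholds = list(alpha = config$alpha, rmseMax = config$rmseMax,
                      maeMax = config$maeMax, mapeMax = config$mapeMax,
                      kmoGate = config$kmoGate, corGate = config$corGate,
                      ccdForm = config$ccdForm, ccdAlpha = config$ccdAlpha),
    inversion = lapply(inversion, function(z)
      list(depth = z$depth, chosen = z$select$method,
           passedGates = z$select$passedGates,
           metrics = z$reports,
           coefficients = as.list(z$model@coefficients),
           intercept = z$model@intercept)),
    veg = list(index = veg$select$index, kmo = veg$kmo,
               bartlettP = veg$bartlett$p,
               weights = as.list(veg$weights)),
    correlation = as.list(corr$proportions),
    coupling = as.list(coup$proportions),
    importance = stats::setNames(as.list(imp$importance$share),
                                 imp$importance$feature))
  if (writeOut) {
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
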