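#' Pipeline configuration with reference defaults
#'
#' Collects every tunable the end-to-end run uses, with the reference
#' defaults of the analysis: significance level 0.05, model-selection
#' error gates RMSE < 0.05 / MAE < 0.02 / MAPE in [0, 20]%, KMO gate
#' 0.5, correlation gate 0.6, geometric-mean coupling with equal
#' subsystem weights, and conventional random-forest settings
#' (500 trees, mtry 2, minimum leaf 5). The configuration round-trips
#' losslessly through [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param nRows,nCols,cellSize basin geometry (64 x 64 cells of 20 m by
#'   default).
#' @param nSites number of soil sampling sites (170).
#' @param noiseSd,gradientStrength generator truth settings, see
#'   [smTruthConfig()].
#' @param years simulated year range.
#' @param seed global seed fanned out to the stages.
#' @param alpha significance level for screening, mapping and
#'   Bartlett's test.
#' @param rmseMax,maeMax,mapeMax model-selection error gates.
#' @param kmoGate,corGate composite-index screening gates.
#' @param ccdForm,ccdAlpha coupling form and vegetation weight.
#' @param nTrees,mtry,minLeaf,maxPixels forest settings.
#' @param splitRatio modeling:validation site ratio.
#' @return a named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(nRows = 64, nCols = 64, cellSize = 20,
                           nSites = 170, noiseSd = 0.01,
                           gradientStrength = 1, years = 2017:2024,
                           seed = 1, alpha = 0.05, rmseMax = 0.05,
                           maeMax = 0.02, mapeMax = 20, kmoGate = 0.5,
                           corGate = 0.6, ccdForm = "sqrt",
                           ccdAlpha = 0.5, nTrees = 500, mtry = 2,
                           minLeaf = 5, maxPixels = 50000,
                           splitRatio = 4) {
  cfg <- list(nRows = nRows, nCols = nCols, cellSize = cellSize,
              nSites = nSites, noiseSd = noiseSd,
              gradientStrength = gradientStrength,
              years = as.integer(years), seed = seed, alpha = alpha,
              rmseMax = rmseMax, maeMax = maeMax, mapeMax = mapeMax,
              kmoGate = kmoGate, corGate = corGate, ccdForm = ccdForm,
              ccdAlpha = ccdAlpha, nTrees = nTrees, mtry = mtry,
              minLeaf = minLeaf, maxPixels = maxPixels,
              splitRatio = splitRatio)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read/write a pipeline configuration as YAML
#'
#' @param config a [pipelineConfig()] list.
#' @param path YAML file path.
#' @return \code{readPipelineConfig} returns the configuration with
#'   defaults filled in for missing fields.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, raw)
}
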