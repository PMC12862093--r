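#' Read and write rasters as ESRI ASCII grids
#'
#' The package's on-disk raster format is the ESRI ASCII grid
#' (\code{.asc}): a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by the cell values, row
#' 1 = northern edge first. Values are written with full double
#' precision so a write/read round trip reproduces the payload
#' bit-exactly; nodata cells (outside the basin mask) are written as
#' the nodata value (-9999 by default) and read back as the mask.
#'
#' @param grid a [RasterGrid-class].
#' @param path file path.
#' @param nodata nodata sentinel written to the file.
#' @return \code{readAsciiGrid} returns a [RasterGrid-class];
#'   \code{writeAsciiGrid} returns the path invisibly.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  g <- geometry(grid)
  v <- gridValues(grid)
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols        %d", g@nCols),
               sprintf("nrows        %d", g@nRows),
               sprintf("xllcorner    %.17g", g@origin[1]),
               sprintf("yllcorner    %.17g", g@origin[2]),
               sprintf("cellsize     %.17g", g@cellSize),
               sprintf("NODATA_value %.17g", nodata)), con)
  for (i in seq_len(g@nRows))
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path))
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  mask <- !is.na(m)
  if (!any(mask)) stop("raster is entirely nodata: ", path)
  geom <- new("BasinGeometry", nRows = nr, nCols = nc,
              cellSize = hdr$cellsize,
              origin = c(hdr$xllcorner, hdr$yllcorner), mask = mask)
  new("RasterGrid", values = m, geometry = geom)
}

#' Write or read a monthly stack as per-month ASCII grids
#'
#' Layers are stored as \code{<var>_<YYYY>_<MM>.asc} inside a
#' directory; reading globs that pattern, orders layers by time and
#' checks that all layers share one geometry.
#'
#' @param stack a [TimeSeriesStack-class].
#' @param dir directory (created if needed).
#' @param variable variable name used in the file pattern.
#' @return \code{writeStackDir}: the directory, invisibly;
#'   \code{readStackDir}: a [TimeSeriesStack-class].
#' @export
writeStackDir <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- stack@geometry
  for (i in seq_len(nLayers(stack))) {
    f <- file.path(dir, sprintf("%s_%04d_%02d.asc", stack@variable,
                                stack@times$year[i], stack@times$month[i]))
    writeAsciiGrid(rasterGrid(stack@layers[[i]], g), f)
  }
  invisible(dir)
}

#' @rdname writeStackDir
#' @export
readStackDir <- function(dir, variable) {
  files <- list.files(dir, pattern = paste0("^", variable,
                                            "_\\d{4}_\\d{2}\\.asc$"),
                      full.names = TRUE)
  if (!length(files)) stop("no layers for variable ", variable, " in ", dir)
  info <- regmatches(basename(files),
                     regexec("_(\\d{4})_(\\d{2})\\.asc$", basename(files)))
  year <- vapply(info, function(x) as.integer(x[2]), integer(1))
  month <- vapply(info, function(x) as.integer(x[3]), integer(1))
  ord <- order(year * 12L + month)
  grids <- lapply(files[ord], readAsciiGrid)
  geom <- geometry(grids[[1]])
  for (gr in grids[-1]) assertSameGeometry(grids[[1]], gr)
  timeSeriesStack(grids, years = year[ord], months = month[ord],
                  variable = variable, geom = geom)
}
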