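#' @include AllGenerics.R
NULL

#' Construct a GridSpec
#'
#' @param cellSize positive square cell edge length in map units.
#' @param nRows,nCols grid dimensions.
#' @param originX,originY projected coordinates of the upper-left corner.
#' @param crs CRS definition (WKT or PROJ string); must be projected.
#' @param nodata integer nodata sentinel.
#' @return a [GridSpec-class] object.
#' @examples
#' g <- GridSpec(30, 10, 10, originX = 0, originY = 300)
#' cellSize(g)
#' @export
GridSpec <- function(cellSize = 30, nRows, nCols,
                     originX = 0, originY = nRows * cellSize,
                     crs = .defaultCRS(), nodata = -2147483647L) {
  checkProjectedCRS(crs)
  new("GridSpec", cellSize = as.numeric(cellSize),
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      originX = as.numeric(originX), originY = as.numeric(originY),
      crs = crs, nodata = as.integer(nodata))
}

# a generic Albers equal-area WKT used by fixtures and examples
.defaultCRS <- function() {
  paste0("PROJCS[\"Albers_Equal_Area_Conic\",",
         "GEOGCS[\"GCS_North_American_1983\",",
         "DATUM[\"D_North_American_1983\",",
         "SPHEROID[\"GRS_1980\",6378137.0,298.257222101]],",
         "PRIMEM[\"Greenwich\",0.0],UNIT[\"Degree\",0.0174532925199433]],",
         "PROJECTION[\"Albers\"],UNIT[\"Meter\",1.0]]")
}

#' Validate that a CRS definition is projected
#'
#' Geographic (latitude/longitude) CRS definitions are rejected: the
#' pipeline requires an equal-area projected CRS and never reprojects
#' silently.
#'
#' @param crs character CRS definition (WKT or PROJ string), or `NA`.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
checkProjectedCRS <- function(crs) {
  if (length(crs) != 1L || is.na(crs) || !nzchar(trimws(crs)))
    stopData("missing CRS: equal-area projected CRS required")
  s <- trimws(crs)
  geographic <- grepl("^(GEOGCS|GEOGCRS)\\b", s, ignore.case = TRUE) ||
    grepl("+proj=longlat", s, fixed = TRUE) ||
    grepl("^EPSG:4326$", s, ignore.case = TRUE)
  if (geographic)
    stopData("geographic CRS rejected: equal-area projected CRS required")
  invisible(TRUE)
}

setMethod("cellSize", "GridSpec", function(x) x@cellSize)
setMethod("gridDim", "GridSpec", function(x) c(x@nRows, x@nCols))
setMethod("crsOf", "GridSpec", function(x) x@crs)

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", object@nRows, "x", object@nCols, "cells of",
      object@cellSize, "m\n")
  cat("  origin (upper-left):", object@originX, ",", object@originY, "\n")
  cat("  nodata:", object@nodata, "\n")
})

#' Cell-center coordinates of a grid
#'
#' Row 1 is the top row; centers are offset half a cell from the upper-left
#' origin.
#'
#' @param grid a [GridSpec-class].
#' @return list with `x` (length nCols) and `y` (length nRows) center
#'   coordinates.
#' @export
cellCenters <- function(grid) {
  cs <- grid@cellSize
  list(x = grid@originX + (seq_len(grid@nCols) - 0.5) * cs,
       y = grid@originY - (seq_len(grid@nRows) - 0.5) * cs)
}

# TRUE if two grids describe the same geometry (used to enforce the
# one-GridSpec-per-run contract).
sameGrid <- function(a, b, tol = 1e-9) {
  a@nRows == b@nRows && a@nCols == b@nCols &&
    abs(a@cellSize - b@cellSize) <= tol &&
    abs(a@originX - b@originX) <= tol &&
    abs(a@originY - b@originY) <= tol
}

.checkSameGrid <- function(a, b, what = "rasters") {
  if (!sameGrid(a, b))
    stopData(sprintf("grid mismatch: all %s in a run must share one GridSpec",
                     what))
  invisible(TRUE)
}

# condition helpers: config errors (CLI exit 2) vs data-contract errors
# (CLI exit 3)
stopConfig <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dasypopConfigError", "dasypopError")))
}

stopData <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dasypopDataError", "dasypopError")))
}
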