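#' @include grid-methods.R
NULL

#' Construct a ClassRaster
#'
#' @param codes integer matrix of class codes (nodata cells carry the grid's
#'   nodata sentinel).
#' @param grid a [GridSpec-class].
#' @param codebook named character vector mapping codes (as names) to
#'   labels; defaults to labels equal to the codes present.
#' @param uninhabitedCode reserved uninhabited class code, or `NA`.
#' @return a [ClassRaster-class].
#' @export
ClassRaster <- function(codes, grid, codebook = NULL,
                        uninhabitedCode = NA_integer_) {
  storage.mode(codes) <- "integer"
  if (is.null(codebook)) {
    vals <- sort(unique(codes[codes != grid@nodata]))
    codebook <- stats::setNames(as.character(vals), as.character(vals))
    if (!is.na(uninhabitedCode) &&
        !as.character(uninhabitedCode) %in% names(codebook)) {
      codebook[as.character(uninhabitedCode)] <- "uninhabited"
    }
  }
  new("ClassRaster", grid = grid, codes = codes,
      uninhabitedCode = as.integer(uninhabitedCode), codebook = codebook)
}

#' Construct a UnitRaster
#' @param unitIds integer matrix of unit ids (nodata sentinel elsewhere).
#' @param grid a [GridSpec-class].
#' @return a [UnitRaster-class].
#' @export
UnitRaster <- function(unitIds, grid) {
  storage.mode(unitIds) <- "integer"
  new("UnitRaster", grid = grid, unitIds = unitIds)
}

#' Construct a SlopeRaster
#' @param percentSlope numeric matrix of percent slopes (`NA` = nodata).
#' @param grid a [GridSpec-class].
#' @return a [SlopeRaster-class].
#' @export
SlopeRaster <- function(percentSlope, grid) {
  storage.mode(percentSlope) <- "double"
  new("SlopeRaster", grid = grid, percentSlope = percentSlope)
}

setMethod("gridSpec", "ClassRaster", function(x) x@grid)
setMethod("gridSpec", "UnitRaster", function(x) x@grid)
setMethod("gridSpec", "SlopeRaster", function(x) x@grid)

setMethod("rasterValues", "ClassRaster", function(x) x@codes)
setMethod("rasterValues", "UnitRaster", function(x) x@unitIds)
setMethod("rasterValues", "SlopeRaster", function(x) x@percentSlope)

setMethod("uninhabitedCode", "ClassRaster", function(x) x@uninhabitedCode)
setMethod("codebook", "ClassRaster", function(x) x@codebook)

setMethod("show", "ClassRaster", function(object) {
  g <- object@grid
  vals <- object@codes[object@codes != g@nodata]
  cat("ClassRaster:", g@nRows, "x", g@nCols, "cells of", g@cellSize, "m\n")
  cat("  classes:", paste(sort(unique(vals)), collapse = " "), "\n")
  if (!is.na(object@uninhabitedCode))
    cat("  uninhabited code:", object@uninhabitedCode, "\n")
  cat("  nodata cells:", sum(object@codes == g@nodata), "\n")
})

setMethod("show", "UnitRaster", function(object) {
  g <- object@grid
  assigned <- object@unitIds != g@nodata
  cat("UnitRaster:", g@nRows, "x", g@nCols, "cells;",
      length(unique(object@unitIds[assigned])), "units on",
      sum(assigned), "cells\n")
})

setMethod("show", "SlopeRaster", function(object) {
  g <- object@grid
  cat("SlopeRaster:", g@nRows, "x", g@nCols, "cells; max slope",
      format(max(object@percentSlope, na.rm = TRUE), digits = 4), "%\n")
})

#' Construct SamplingCriteria
#'
#' Eligibility thresholds for sampling representative (homogeneous) blocks:
#' at least `coverageThreshold` of the unit's rasterized area in one class
#' (inclusive), at least `minCells` cells, and at least `minSamples`
#' qualifying blocks before the class counts as sampled.
#'
#' @param coverageThreshold fraction in (0, 1]; default 0.95.
#' @param minCells integer; default 2 (area strictly greater than one cell).
#' @param minSamples integer; default 3.
#' @return a [SamplingCriteria-class].
#' @export
SamplingCriteria <- function(coverageThreshold = 0.95, minCells = 2L,
                             minSamples = 3L) {
  new("SamplingCriteria", coverageThreshold = as.numeric(coverageThreshold),
      minCells = as.integer(minCells), minSamples = as.integer(minSamples))
}

setMethod("show", "SamplingCriteria", function(object) {
  cat("SamplingCriteria: coverage >=", object@coverageThreshold,
      "; cells >=", object@minCells,
      "; blocks >=", object@minSamples, "\n")
})
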