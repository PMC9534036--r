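#' @import methods
NULL

#' GridSpec: common raster geometry
#'
#' Defines the regular grid every raster in a run must conform to: square
#' cell size, dimensions, the projected coordinates of the grid's upper-left
#' corner, the CRS (WKT or PROJ string of an equal-area projected CRS), and
#' the integer nodata sentinel.
#'
#' @slot cellSize positive cell edge length in map units (metres; 30 for the
#'   land-cover convention, giving 900 m^2 cells).
#' @slot nRows,nCols grid dimensions.
#' @slot originX,originY projected coordinates of the upper-left corner.
#' @slot crs character CRS definition; must describe a projected CRS.
#' @slot nodata integer sentinel for cells carrying no value.
#' @export
setClass("GridSpec",
  representation(cellSize = "numeric",
                 nRows = "integer",
                 nCols = "integer",
                 originX = "numeric",
                 originY = "numeric",
                 crs = "character",
                 nodata = "integer"),
  prototype(cellSize = 30, nRows = 1L, nCols = 1L,
            originX = 0, originY = 30,
            crs = "PROJCS[\"unspecified equal-area\"]",
            nodata = -2147483647L))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "grid must have at least one row and one column")
  if (length(object@crs) != 1L || is.na(object@crs) || !nzchar(object@crs))
    msg <- c(msg, "crs must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' ClassRaster: integer class codes on a grid
#'
#' Class-coded ancillary raster (land-cover style) with an optional reserved
#' uninhabited code and a codebook mapping codes to labels.
#'
#' @slot grid the [GridSpec-class] the codes conform to.
#' @slot codes integer matrix, `nRows x nCols`; nodata cells carry the
#'   grid's nodata sentinel.
#' @slot uninhabitedCode reserved integer code for the uninhabited class
#'   (`NA` until [reclassifyAncillary()] assigns one).
#' @slot codebook named character vector, names are codes as strings.
#' @export
setClass("ClassRaster",
  representation(grid = "GridSpec",
                 codes = "matrix",
                 uninhabitedCode = "integer",
                 codebook = "character"))

setValidity("ClassRaster", function(object) {
  msg <- character()
  g <- object@grid
  if (!identical(dim(object@codes), c(g@nRows, g@nCols)))
    msg <- c(msg, "codes matrix does not match grid dimensions")
  if (!is.integer(object@codes))
    msg <- c(msg, "codes must be an integer matrix")
  vals <- unique(object@codes[object@codes != g@nodata])
  if (length(object@codebook)) {
    known <- as.integer(names(object@codebook))
    if (!all(vals %in% known))
      msg <- c(msg, "every non-nodata code must appear in the codebook")
    if (!is.na(object@uninhabitedCode) &&
        !(object@uninhabitedCode %in% known))
      msg <- c(msg, "uninhabitedCode must appear in the codebook")
  }
  if (!is.na(object@uninhabitedCode) &&
      object@uninhabitedCode == g@nodata)
    msg <- c(msg, "uninhabitedCode collides with the nodata sentinel")
  if (length(msg)) msg else TRUE
})

#' UnitRaster: source-unit ids on a grid
#'
#' A cell carries the id of the source unit whose interior (or boundary,
#' ties to the smaller id) contains the cell center; nodata elsewhere.
#'
#' @slot grid the [GridSpec-class].
#' @slot unitIds integer matrix of unit ids.
#' @export
setClass("UnitRaster",
  representation(grid = "GridSpec",
                 unitIds = "matrix"))

setValidity("UnitRaster", function(object) {
  g <- object@grid
  if (!identical(dim(object@unitIds), c(g@nRows, g@nCols)))
    return("unitIds matrix does not match grid dimensions")
  if (!is.integer(object@unitIds))
    return("unitIds must be an integer matrix")
  TRUE
})

#' SlopeRaster: percent slope on a grid
#'
#' Percent slope (rise/run x 100) per cell; consumed, never computed, by
#' this package.
#'
#' @slot grid the [GridSpec-class].
#' @slot percentSlope numeric matrix of non-negative percent slopes
#'   (`NA` = nodata).
#' @export
setClass("SlopeRaster",
  representation(grid = "GridSpec",
                 percentSlope = "matrix"))

setValidity("SlopeRaster", function(object) {
  g <- object@grid
  if (!identical(dim(object@percentSlope), c(g@nRows, g@nCols)))
    return("percentSlope matrix does not match grid dimensions")
  if (any(object@percentSlope < 0, na.rm = TRUE))
    return("percent slope must be non-negative")
  TRUE
})

#' FeatureSet: vector features with attributes
#'
#' A set of polygon or line features in a projected CRS with an attribute
#' table. Polygon geometries are multipolygons (lists of rings under the
#' even-odd rule); line geometries are lists of open paths.
#'
#' @slot geoms list of geometries, one per feature.
#' @slot data data.frame of feature attributes (one row per feature).
#' @slot geomType `"polygon"` or `"line"`.
#' @slot crs character CRS definition.
#' @export
setClass("FeatureSet",
  representation(geoms = "list",
                 data = "data.frame",
                 geomType = "character",
                 crs = "character"))

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (length(object@geoms) != nrow(object@data))
    msg <- c(msg, "geoms and data must have one entry per feature")
  if (!object@geomType %in% c("polygon", "line"))
    msg <- c(msg, "geomType must be 'polygon' or 'line'")
  if (length(msg)) msg else TRUE
})

#' SourceUnits: population-bearing polygons with nested admin ids
#'
#' Census-block style source units. The attribute table carries `unitId`
#' (unique positive integer), `population` (non-negative count), nested
#' `tractId`, `countyId`, `stateId` identifiers, and the processing
#' `zoneId`.
#'
#' @slot data data.frame with the columns above.
#' @slot geoms list of multipolygons, one per unit.
#' @slot crs character CRS definition.
#' @export
setClass("SourceUnits",
  representation(data = "data.frame",
                 geoms = "list",
                 crs = "character"))

.SOURCE_UNIT_COLS <- c("unitId", "population", "tractId", "countyId",
                       "stateId", "zoneId")

setValidity("SourceUnits", function(object) {
  msg <- character()
  d <- object@data
  missing <- setdiff(.SOURCE_UNIT_COLS, names(d))
  if (length(missing))
    msg <- c(msg, paste("missing columns:", paste(missing, collapse = ", ")))
  else {
    if (anyDuplicated(d$unitId))
      msg <- c(msg, "unitId must be unique")
    if (any(d$population < 0))
      msg <- c(msg, "population must be non-negative")
    if (any(d$unitId <= 0))
      msg <- c(msg, "unitId must be positive integers")
    if (any(is.na(d$tractId)) || any(is.na(d$zoneId)))
      msg <- c(msg, "every unit needs a tractId and a zoneId")
  }
  if (length(object@geoms) != nrow(d))
    msg <- c(msg, "one geometry per unit required")
  if (length(msg)) msg else TRUE
})

#' SamplingCriteria: eligibility thresholds for representative blocks
#'
#' @slot coverageThreshold minimum fraction of a unit's rasterized area in
#'   one class for the unit to be representative of it (default 0.95,
#'   inclusive).
#' @slot minCells minimum rasterized area in cells (default 2; strictly more
#'   than one pixel).
#' @slot minSamples minimum number of representative blocks before a class
#'   counts as sampled (default 3).
#' @export
setClass("SamplingCriteria",
  representation(coverageThreshold = "numeric",
                 minCells = "integer",
                 minSamples = "integer"),
  prototype(coverageThreshold = 0.95, minCells = 2L, minSamples = 3L))

setValidity("SamplingCriteria", function(object) {
  msg <- character()
  if (object@coverageThreshold <= 0 || object@coverageThreshold > 1)
    msg <- c(msg, "coverageThreshold must be in (0, 1]")
  if (object@minSamples < 1L)
    msg <- c(msg, "minSamples must be >= 1")
  if (object@minCells < 1L)
    msg <- c(msg, "minCells must be >= 1")
  if (length(msg)) msg else TRUE
})
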