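#' @include geodata-io.R
NULL

#' Rasterize polygons by the cell-center rule
#'
#' A cell carries attribute `v` iff the cell's center point falls inside
#' (or on the boundary of) a polygon with attribute `v`; cells covered by
#' no polygon are nodata. When a center lies exactly on a boundary shared
#' by two polygons, the smaller attribute id wins, which makes the result
#' deterministic and independent of input ordering. Polygons so small or
#' thin that they contain no cell center produce no cells at all.
#'
#' @param geoms list of multipolygons.
#' @param ids positive integer attribute per polygon.
#' @param grid target [GridSpec-class].
#' @param crs CRS of the polygons; must match the grid's.
#' @return a [UnitRaster-class].
#' @export
rasterizePolygons <- function(geoms, ids, grid, crs = grid@crs) {
  if (!identical(crs, grid@crs))
    stopData("CRS mismatch: polygons are not in the grid's CRS")
  if (any(ids != as.integer(ids)) || any(ids <= 0))
    stopData("polygon attribute must be positive integers")
  ids <- as.integer(ids)
  out <- matrix(grid@nodata, grid@nRows, grid@nCols)
  centers <- cellCenters(grid)
  cs <- grid@cellSize
  # descending id order: smaller ids written last win boundary ties
  for (k in order(ids, decreasing = TRUE)) {
    g <- geoms[[k]]
    if (geomIsEmpty(g)) next
    bb <- geomBBox(g)
    cols <- which(centers$x >= bb["xmin"] - cs & centers$x <= bb["xmax"] + cs)
    rows <- which(centers$y >= bb["ymin"] - cs & centers$y <= bb["ymax"] + cs)
    if (!length(cols) || !length(rows)) next
    xp <- rep(centers$x[cols], each = length(rows))
    yp <- rep(centers$y[rows], times = length(cols))
    inside <- geomContains(xp, yp, g)
    if (!any(inside)) next
    idx <- cbind(rep(rows, times = length(cols))[inside],
                 rep(cols, each = length(rows))[inside])
    out[idx] <- ids[k]
  }
  UnitRaster(out, grid)
}

# cell count per id after rasterization (named integer vector; ids with no
# cells are absent)
.rasterCellCounts <- function(unitRaster) {
  ids <- unitRaster@unitIds
  ids <- ids[ids != unitRaster@grid@nodata]
  table(ids)
}

#' Rasterize a polygon set to a logical mask
#'
#' Cell-center rule as in [rasterizePolygons()], but returns a single
#' logical matrix marking cells covered by any polygon in the set.
#'
#' @param geoms list of multipolygons (or a single multipolygon).
#' @param grid target [GridSpec-class].
#' @return logical matrix `nRows x nCols`.
#' @export
rasterizeMask <- function(geoms, grid) {
  if (length(geoms) && .isRing(geoms[[1L]])) geoms <- list(geoms)
  out <- matrix(FALSE, grid@nRows, grid@nCols)
  centers <- cellCenters(grid)
  cs <- grid@cellSize
  for (g in geoms) {
    if (geomIsEmpty(g)) next
    bb <- geomBBox(g)
    cols <- which(centers$x >= bb["xmin"] - cs & centers$x <= bb["xmax"] + cs)
    rows <- which(centers$y >= bb["ymin"] - cs & centers$y <= bb["ymax"] + cs)
    if (!length(cols) || !length(rows)) next
    xp <- rep(centers$x[cols], each = length(rows))
    yp <- rep(centers$y[rows], times = length(cols))
    inside <- geomContains(xp, yp, g)
    if (!any(inside)) next
    idx <- cbind(rep(rows, times = length(cols))[inside],
                 rep(cols, each = length(rows))[inside])
    out[idx] <- TRUE
  }
  out
}
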