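#' @include uninhabited.R
NULL

#' Reclassify land cover with uninhabited evidence
#'
#' Produces the IDM ancillary raster: a cell becomes the reserved
#' uninhabited code where the dissolved uninhabited features cover its
#' center, where any extra binary mask is set (e.g., primary-road or
#' energy-production cells pre-extracted from an imperviousness
#' descriptor), or where percent slope strictly exceeds
#' `slopeThreshold` (25% by default). All other cells keep their original
#' land-cover code; nodata propagates.
#'
#' @param landcover a [ClassRaster-class].
#' @param uninhabited a polygon [FeatureSet-class] (or `NULL`).
#' @param extraMasks list of logical matrices or binary [ClassRaster-class]
#'   objects conforming to the grid.
#' @param slope a [SlopeRaster-class] or `NULL`.
#' @param slopeThreshold percent slope above which a cell is uninhabited
#'   (strict inequality; default 25).
#' @param uninhabitedCode reserved code; default one more than the largest
#'   land-cover code. Must not collide with an existing code.
#' @return a [ClassRaster-class] with `uninhabitedCode` set.
#' @export
reclassifyAncillary <- function(landcover, uninhabited = NULL,
                                extraMasks = list(), slope = NULL,
                                slopeThreshold = 25,
                                uninhabitedCode = NULL) {
  g <- landcover@grid
  codes <- landcover@codes
  existing <- unique(codes[codes != g@nodata])
  if (is.null(uninhabitedCode))
    uninhabitedCode <- max(existing, 0L) + 1L
  uninhabitedCode <- as.integer(uninhabitedCode)
  if (uninhabitedCode %in% existing &&
      !identical(uninhabitedCode, landcover@uninhabitedCode))
    stopData("uninhabited code %d collides with an existing land-cover code",
             uninhabitedCode)
  mask <- matrix(FALSE, g@nRows, g@nCols)
  if (!is.null(uninhabited) && length(uninhabited@geoms))
    mask <- mask | rasterizeMask(uninhabited@geoms, g)
  for (m in extraMasks) {
    if (is(m, "ClassRaster")) {
      .checkSameGrid(g, m@grid)
      m <- m@codes != 0L & m@codes != m@grid@nodata
    }
    if (!identical(dim(m), c(g@nRows, g@nCols)))
      stopData("extra mask does not conform to the grid")
    mask <- mask | (m & !is.na(m))
  }
  if (!is.null(slope)) {
    .checkSameGrid(g, slope@grid)
    mask <- mask | (.gtGuard(slope@percentSlope, slopeThreshold) &
                      !is.na(slope@percentSlope))
  }
  nodata <- codes == g@nodata
  codes[mask & !nodata] <- uninhabitedCode
  cb <- landcover@codebook
  cb[as.character(uninhabitedCode)] <- "uninhabited"
  ClassRaster(codes, g, codebook = cb, uninhabitedCode = uninhabitedCode)
}

#' Summarize a reclassification
#'
#' Counts, per original land-cover code, the cells reassigned to the
#' uninhabited code; the total equals the number of mismatching non-nodata
#' cells.
#'
#' @param before,after [ClassRaster-class] objects on one grid.
#' @return data.frame with `code`, `label`, `cellsReclassified`; attribute
#'   `total` carries the grand total.
#' @export
summarizeReclassification <- function(before, after) {
  .checkSameGrid(before@grid, after@grid)
  nodata <- before@grid@nodata
  valid <- before@codes != nodata & after@codes != after@grid@nodata
  changed <- valid & before@codes != after@codes
  origCodes <- sort(unique(before@codes[valid]))
  counts <- vapply(origCodes, function(cd)
    sum(changed & before@codes == cd), integer(1))
  labels <- before@codebook[as.character(origCodes)]
  labels[is.na(labels)] <- as.character(origCodes[is.na(labels)])
  out <- data.frame(code = origCodes, label = unname(labels),
                    cellsReclassified = counts)
  attr(out, "total") <- sum(counts)
  out
}
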