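# shared fixture helpers; everything is generated in code

# a grid with 30 m cells, origin at (0, nRows*30)
testGrid <- function(nRows = 10, nCols = 10, cellSize = 30) {
  GridSpec(cellSize, nRows, nCols, originX = 0, originY = nRows * cellSize)
}

# line FeatureSet from a single path
lineSet <- function(x, y, data = NULL, crs = testGrid()@crs) {
  if (is.null(data)) data <- data.frame(name = "line1")
  FeatureSet(list(list(list(x = x, y = y))), data,
             geomType = "line", crs = crs)
}

# polygon FeatureSet from rectangles given as list(c(x0, y0, w, h), ...)
rectSet <- function(rects, data = NULL, crs = testGrid()@crs) {
  geoms <- lapply(rects, function(r) geomRect(r[1], r[2], r[3], r[4]))
  if (is.null(data))
    data <- data.frame(category = paste0("f", seq_along(rects)),
                       mixedUse = FALSE)
  FeatureSet(geoms, data, geomType = "polygon", crs = crs)
}

# SourceUnits from rectangles + populations, single tract by default
rectUnits <- function(rects, populations,
                      tractId = rep("T1", length(rects)),
                      zoneId = rep("Z1", length(rects)),
                      crs = testGrid()@crs) {
  geoms <- lapply(rects, function(r) geomRect(r[1], r[2], r[3], r[4]))
  SourceUnits(data.frame(unitId = seq_along(rects),
                         population = populations,
                         tractId = tractId,
                         countyId = zoneId, stateId = zoneId,
                         zoneId = zoneId),
              geoms, crs = crs)
}

# per-cell brute-force allocation oracle: weight each cell by its class
# density, normalize within the unit, multiply by y_b; returns per-cell
# population matrix
bruteForceAllocation <- function(unitRaster, ancillary, populations,
                                 densities, unitIds = NULL) {
  g <- unitRaster@grid
  u <- as.vector(unitRaster@unitIds)
  a <- as.vector(ancillary@codes)
  out <- rep(NA_real_, length(u))
  loopIds <- unique(u[u != g@nodata])
  if (!is.null(unitIds)) loopIds <- intersect(loopIds, unitIds)
  for (uid in loopIds) {
    sel <- which(u == uid & a != ancillary@grid@nodata)
    if (!length(sel)) next
    w <- densities[as.character(a[sel])]
    y <- populations[[as.character(uid)]]
    out[sel] <- if (sum(w) > 0) y * w / sum(w) else y / length(sel)
  }
  matrix(out, g@nRows, g@nCols)
}

# run the full chain on a scenario bundle: merge, reclassify, allocate
runScenarioChain <- function(bundle, uninhabited = NULL, criteria = SamplingCriteria()) {
  units <- suppressMessages(mergeSmallUnits(bundle$blocks, bundle$grid))
  anc <- reclassifyAncillary(bundle$landscape, uninhabited = uninhabited)
  run <- suppressWarnings(
    runZones(units, anc, zeroClasses = bundle$scenario$zeroClasses,
             criteria = criteria))
  list(units = units, ancillary = anc, run = run)
}
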