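#' @include ancillary.R
NULL

# Source-unit preparation: units too small or awkwardly placed to own any
# cell center would silently lose their population at rasterization, so
# populated ones are dissolved into a qualifying same-tract neighbor first.

#' Find populated units not represented on the grid
#'
#' Ids of units with population > 0 whose joint rasterization (cell-center
#' rule, smaller-id ties) yields zero cells.
#'
#' @param units a [SourceUnits-class].
#' @param grid the [GridSpec-class].
#' @return integer vector of unit ids.
#' @export
findUnrepresentedUnits <- function(units, grid) {
  ur <- rasterizeSourceUnits(units, grid, checkMerged = FALSE)
  counts <- .rasterCellCounts(ur)
  represented <- as.integer(names(counts))
  d <- units@data
  sort(d$unitId[d$population > 0 & !(d$unitId %in% represented)])
}

#' Merge unrepresented populated units into neighbors
#'
#' Each populated unit owning no cell center is dissolved into the
#' same-tract neighbor that (1) shares the longest border and (2) has
#' population greater than zero; when no populated same-tract neighbor
#' exists, criterion (2) is dropped. The recipient absorbs the donor's
#' population, so the total is conserved exactly and no population crosses
#' a tract boundary. Ties on border length go to the smaller neighbor id;
#' donors are processed in ascending id order and merging iterates until
#' no populated unit is unrepresented. A donor with no same-tract neighbor
#' at all is left in place and flagged unallocatable.
#'
#' @param units a [SourceUnits-class].
#' @param grid the [GridSpec-class].
#' @return a [SourceUnits-class]; attribute `unallocatableIds` lists units
#'   left without cells.
#' @export
mergeSmallUnits <- function(units, grid) {
  repeat {
    donors <- findUnrepresentedUnits(units, grid)
    d <- units@data
    unallocatable <- integer()
    merged <- FALSE
    for (donorId in donors) {
      di <- match(donorId, d$unitId)
      if (is.na(di)) next       # already absorbed in this pass
      donorGeom <- units@geoms[[di]]
      sameTract <- which(d$tractId == d$tractId[di] & d$unitId != donorId)
      if (!length(sameTract)) {
        unallocatable <- c(unallocatable, donorId)
        message(sprintf(
          "unit %d has no same-tract neighbor; population %g unallocatable",
          donorId, d$population[di]))
        next
      }
      borders <- vapply(sameTract, function(j)
        sharedBorderLength(donorGeom, units@geoms[[j]]), numeric(1))
      touching <- borders > 0
      if (!any(touching)) {
        unallocatable <- c(unallocatable, donorId)
        message(sprintf(
          "unit %d touches no same-tract neighbor; population %g unallocatable",
          donorId, d$population[di]))
        next
      }
      cand <- sameTract[touching]
      candBorders <- borders[touching]
      populated <- d$population[cand] > 0
      if (any(populated)) {
        cand <- cand[populated]
        candBorders <- candBorders[populated]
      }
      best <- cand[candBorders == max(candBorders)]
      recipient <- best[which.min(d$unitId[best])]
      # dissolve donor into recipient
      units@geoms[[recipient]] <- geomUnion(units@geoms[[recipient]],
                                            donorGeom)
      d$population[recipient] <- d$population[recipient] + d$population[di]
      d <- d[-di, , drop = FALSE]
      units@geoms <- units@geoms[-di]
      units@data <- d
      d <- units@data
      merged <- TRUE
      # recompute indices next donor via match() above
    }
    units@data <- d
    if (!merged) break
  }
  attr(units, "unallocatableIds") <- unallocatable
  units
}

#' Rasterize source units
#'
#' Cell-center rasterization of the (merged) source units. After
#' [mergeSmallUnits()], every populated unit owns at least one cell or was
#' flagged unallocatable.
#'
#' @param units a [SourceUnits-class].
#' @param grid the [GridSpec-class].
#' @param checkMerged warn about populated zero-cell units (default TRUE).
#' @return a [UnitRaster-class].
#' @export
rasterizeSourceUnits <- function(units, grid, checkMerged = TRUE) {
  ur <- rasterizePolygons(units@geoms, units@data$unitId, grid,
                          crs = units@crs)
  if (checkMerged) {
    counts <- .rasterCellCounts(ur)
    d <- units@data
    missing <- d$unitId[d$population > 0 &
                          !(d$unitId %in% as.integer(names(counts)))]
    if (length(missing))
      warning(sprintf(
        "%d populated unit(s) own no cells (unallocatable): %s",
        length(missing), paste(missing, collapse = ", ")))
  }
  ur
}
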