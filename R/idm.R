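#' @include source-units.R
NULL

# The IDM estimator. All areas are rasterized cell counts, so densities
# are persons per cell ("people per pixel" at 30 m: one cell = 900 m^2).
#
# Notation (one zone): y_b = recorded population of source unit b;
# A_t = cell count of target unit t (one unit x one ancillary class);
# D_c = representative density of class c, obtained by preset, sampling
# (ratio of sums over homogeneous blocks), or intelligent areal weighting
# (IAW) from the population left after preset/sampled classes are debited.

#' Tabulate target units
#'
#' The spatial intersection of source units and ancillary classes: one
#' record per (unit, class) pair with its joint cell count. Per-unit cell
#' counts sum to the unit's total cell count.
#'
#' @param units a [UnitRaster-class].
#' @param ancillary a [ClassRaster-class] on the same grid.
#' @return data.frame with `unitId`, `classCode`, `cells`; attribute
#'   `flaggedUnits` lists units whose every cell has nodata ancillary.
#' @export
tabulateTargetUnits <- function(units, ancillary) {
  .checkSameGrid(units@grid, ancillary@grid)
  u <- as.vector(units@unitIds)
  a <- as.vector(ancillary@codes)
  keepUnit <- u != units@grid@nodata
  bothValid <- keepUnit & a != ancillary@grid@nodata
  if (!any(bothValid)) {
    out <- data.frame(unitId = integer(), classCode = integer(),
                      cells = integer())
    attr(out, "flaggedUnits") <- sort(unique(u[keepUnit]))
    return(out)
  }
  tab <- table(unitId = u[bothValid], classCode = a[bothValid])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, ]
  out <- data.frame(unitId = as.integer(df$unitId),
                    classCode = as.integer(df$classCode),
                    cells = as.integer(df$Freq))
  out <- out[order(out$unitId, out$classCode), ]
  rownames(out) <- NULL
  attr(out, "flaggedUnits") <-
    setdiff(sort(unique(u[keepUnit])), unique(out$unitId))
  out
}

#' Select representative blocks for a class
#'
#' Units whose rasterized area is at least `minCells` cells and whose
#' fraction of cells in `classCode` is at least the coverage threshold
#' (inclusive at exactly the threshold).
#'
#' @param targets target-unit table from [tabulateTargetUnits()].
#' @param classCode ancillary class code.
#' @param criteria a [SamplingCriteria-class].
#' @return integer vector of qualifying unit ids.
#' @export
selectRepresentativeBlocks <- function(targets, classCode,
                                       criteria = SamplingCriteria()) {
  totals <- tapply(targets$cells, targets$unitId, sum)
  inClass <- targets[targets$classCode == classCode, ]
  if (!nrow(inClass)) return(integer())
  ab <- totals[as.character(inClass$unitId)]
  frac <- inClass$cells / ab
  ok <- .geGuard(frac, criteria@coverageThreshold) & ab >= criteria@minCells
  sort(inClass$unitId[ok])
}

#' Sampled representative density (ratio of sums)
#'
#' The density of a sampled class is the summed population of its
#' representative blocks divided by their summed cell counts -- a ratio of
#' sums, not a mean of per-block ratios, so large empty blocks correctly
#' dilute the estimate.
#'
#' @param populations y_b of the representative blocks.
#' @param cells A_b of the representative blocks.
#' @return persons per cell (numeric scalar).
#' @examples
#' estimateSampledDensity(c(10, 0), c(5, 45))  # 0.2, not mean-of-ratios 1.0
#' @export
estimateSampledDensity <- function(populations, cells) {
  if (length(populations) != length(cells))
    stopData("populations and cells must align")
  sum(populations) / sum(cells)
}

#' Remaining population after preset and sampled classes
#'
#' G_b = y_b minus the population implied by preset/sampled densities over
#' the unit's target cells; may be negative when those densities
#' over-predict the unit.
#'
#' @param population y_b.
#' @param targetCells named numeric vector: cells per class code within the
#'   unit.
#' @param knownDensities named numeric vector of preset/sampled densities
#'   (names are class codes); classes absent from it are ignored.
#' @return numeric scalar G_b.
#' @export
computeRemainder <- function(population, targetCells, knownDensities) {
  k <- intersect(names(targetCells), names(knownDensities))
  population - sum(knownDensities[k] * targetCells[k])
}

#' Initial allocation to unsampled target units
#'
#' Areal weighting of the non-negative remainder over the unit's unsampled
#' targets; a negative remainder allocates zero (never negative
#' population).
#'
#' @param remainder G_b.
#' @param unsampledCells numeric vector of cell counts of the unit's
#'   unsampled targets.
#' @return numeric vector of initial estimates, aligned to
#'   `unsampledCells`.
#' @export
initialUnsampledAllocation <- function(remainder, unsampledCells) {
  if (!length(unsampledCells)) return(numeric())
  if (remainder < 0) return(rep(0, length(unsampledCells)))
  remainder * unsampledCells / sum(unsampledCells)
}

#' IAW representative density for an unsampled class
#'
#' Single pass: initial allocations to the class's targets across the zone,
#' summed and divided by the summed cells.
#'
#' @param initialEstimates initial populations of the zone's targets of the
#'   class.
#' @param cells their cell counts.
#' @return persons per cell.
#' @export
estimateIawDensity <- function(initialEstimates, cells) {
  sum(initialEstimates) / sum(cells)
}

#' Build the density table for one zone
#'
#' Every ancillary class present in the zone receives exactly one
#' representative density with provenance: `preset` (zero-density classes
#' such as open water, perennial ice/snow, emergent herbaceous wetlands,
#' the reserved uninhabited class, plus any user preset or override),
#' `sampled` (ratio of sums over at least `minSamples` representative
#' blocks), or `iaw` (intelligent areal weighting of the remainder).
#' Precedence: preset/override over sampled over IAW. An override for a
#' class absent from the zone warns; a negative density errors.
#'
#' @param targets target-unit table for the zone.
#' @param populations named numeric vector: y_b by unit id (as names).
#' @param presets named numeric vector of preset densities by class code.
#' @param overrides named numeric vector of manual overrides by class code
#'   (e.g., replacing an implausible IAW estimate with a density taken from
#'   other zones).
#' @param criteria a [SamplingCriteria-class].
#' @param zoneId zone label recorded in the output.
#' @return data.frame with `zoneId`, `classCode`, `density`, `method`,
#'   `nSampleBlocks`, `sampledPop`, `sampledCells`.
#' @export
buildDensityTable <- function(targets, populations,
                              presets = numeric(), overrides = numeric(),
                              criteria = SamplingCriteria(),
                              zoneId = "zone") {
  fixed <- presets
  if (length(overrides)) fixed[names(overrides)] <- overrides
  if (any(fixed < 0))
    stopData("preset/override densities must be non-negative")
  classes <- sort(unique(targets$classCode))
  absent <- setdiff(as.integer(names(overrides)), classes)
  if (length(absent))
    warning(sprintf("override for class(es) %s absent from zone %s",
                    paste(absent, collapse = ", "), zoneId))
  totals <- tapply(targets$cells, targets$unitId, sum)

  res <- data.frame(zoneId = zoneId, classCode = classes,
                    density = NA_real_, method = NA_character_,
                    nSampleBlocks = NA_integer_,
                    sampledPop = NA_real_, sampledCells = NA_real_)
  # 1. presets / overrides
  for (i in seq_along(classes)) {
    key <- as.character(classes[i])
    if (key %in% names(fixed)) {
      res$density[i] <- fixed[[key]]
      res$method[i] <- "preset"
    }
  }
  # 2. sampling
  for (i in seq_along(classes)) {
    if (!is.na(res$method[i])) next
    reps <- selectRepresentativeBlocks(targets, classes[i], criteria)
    if (length(reps) >= criteria@minSamples) {
      y <- populations[as.character(reps)]
      ab <- totals[as.character(reps)]
      res$density[i] <- estimateSampledDensity(y, ab)
      res$method[i] <- "sampled"
      res$nSampleBlocks[i] <- length(reps)
      res$sampledPop[i] <- sum(y)
      res$sampledCells[i] <- sum(ab)
    }
  }
  # 3. IAW for the rest (Eqs. 2-4, single pass)
  open <- which(is.na(res$method))
  if (length(open)) {
    known <- stats::setNames(res$density[!is.na(res$method)],
                             as.character(res$classCode[!is.na(res$method)]))
    openCodes <- res$classCode[open]
    initials <- stats::setNames(numeric(length(open)),
                                as.character(openCodes))
    cellsSum <- stats::setNames(numeric(length(open)),
                                as.character(openCodes))
    for (uid in unique(targets$unitId)) {
      tu <- targets[targets$unitId == uid, ]
      tc <- stats::setNames(as.numeric(tu$cells), as.character(tu$classCode))
      gb <- computeRemainder(populations[[as.character(uid)]], tc, known)
      unsampledKeys <- intersect(names(tc), as.character(openCodes))
      if (!length(unsampledKeys)) next
      yInit <- initialUnsampledAllocation(gb, tc[unsampledKeys])
      initials[unsampledKeys] <- initials[unsampledKeys] + yInit
      cellsSum[unsampledKeys] <- cellsSum[unsampledKeys] + tc[unsampledKeys]
    }
    for (i in open) {
      key <- as.character(res$classCode[i])
      res$density[i] <- if (cellsSum[[key]] > 0)
        estimateIawDensity(initials[[key]], cellsSum[[key]]) else 0
      res$method[i] <- "iaw"
    }
  }
  res
}

#' Allocate a unit's population to its target units
#'
#' Mass-preserving allocation: targets are weighted by cell count times
#' class density; when every density in the unit is zero the allocation
#' falls back to pure areal weighting so recorded population is never
#' lost. The target populations sum to y_b exactly (to float tolerance).
#'
#' @param population y_b.
#' @param cells A_t per target.
#' @param densities representative density of each target's class.
#' @return numeric vector of allocated populations, aligned to `cells`.
#' @examples
#' allocatePopulation(100, c(10, 50), c(5, 0.2))  # c(83.33, 16.67)
#' allocatePopulation(12, c(3, 1), c(0, 0))       # areal fallback c(9, 3)
#' @export
allocatePopulation <- function(population, cells, densities) {
  if (length(cells) != length(densities))
    stopData("cells and densities must align")
  if (!length(cells)) return(numeric())
  w <- cells * densities
  total <- sum(w)
  if (total > 0) population * w / total
  else population * cells / sum(cells)
}

#' Per-target densities and the density raster
#'
#' d_t = allocated population / cells; every cell of a target carries its
#' target's density, nodata elsewhere.
#'
#' @param targets target table with `unitId`, `classCode`, `cells`,
#'   `allocated`.
#' @param units a [UnitRaster-class].
#' @param ancillary the [ClassRaster-class] used for tabulation.
#' @return list with `targets` (the table plus a `density` column) and
#'   `raster` (numeric matrix, `NA` = nodata).
#' @export
computeDensity <- function(targets, units, ancillary) {
  .checkSameGrid(units@grid, ancillary@grid)
  targets$density <- ifelse(targets$cells > 0,
                            targets$allocated / targets$cells, 0)
  g <- units@grid
  u <- as.vector(units@unitIds)
  a <- as.vector(ancillary@codes)
  raster <- rep(NA_real_, length(u))
  valid <- u != g@nodata & a != ancillary@grid@nodata
  key <- paste(u[valid], a[valid])
  lookup <- stats::setNames(targets$density,
                            paste(targets$unitId, targets$classCode))
  raster[valid] <- lookup[key]
  list(targets = targets,
       raster = matrix(raster, g@nRows, g@nCols))
}
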