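#' @include idm.R
NULL

#' IdmRun: result of a dasymetric allocation
#'
#' @slot density numeric matrix of persons per cell (`NA` = nodata).
#' @slot densityTables per-zone density table (rows stacked).
#' @slot targets target-unit table with allocations and densities.
#' @slot unitRaster the [UnitRaster-class] used.
#' @slot ancillary the [ClassRaster-class] used.
#' @slot summary list: totals, unallocatable population, provenance tally.
#' @export
setClass("IdmRun",
  representation(density = "matrix",
                 densityTables = "data.frame",
                 targets = "data.frame",
                 unitRaster = "UnitRaster",
                 ancillary = "ClassRaster",
                 summary = "list"))

#' @export
setGeneric("densityRaster", function(x) standardGeneric("densityRaster"))
#' @export
setGeneric("densityTables", function(x) standardGeneric("densityTables"))
#' @export
setGeneric("targetUnits", function(x) standardGeneric("targetUnits"))
#' @export
setGeneric("runSummary", function(x) standardGeneric("runSummary"))

setMethod("densityRaster", "IdmRun", function(x) x@density)
setMethod("densityTables", "IdmRun", function(x) x@densityTables)
setMethod("targetUnits", "IdmRun", function(x) x@targets)
setMethod("runSummary", "IdmRun", function(x) x@summary)

setMethod("show", "IdmRun", function(object) {
  s <- object@summary
  cat("IdmRun:", s$nUnits, "units,", nrow(object@densityTables),
      "zone-class densities\n")
  cat("  population:", format(s$totalPopulation, big.mark = ","),
      " allocated:", format(s$allocatedPopulation, big.mark = ","),
      " unallocatable:", format(s$unallocatablePopulation, big.mark = ","),
      "\n")
  cat("  provenance:",
      paste(names(s$provenance), s$provenance, collapse = ", "), "\n")
  cat("  max pycnophylactic error:",
      format(s$maxPycnophylacticError, digits = 3), "\n")
})

#' Default preset densities
#'
#' Classes asserted to hold zero residential population before any
#' sampling: the reserved uninhabited class plus the configured zero
#' classes (by convention open water, perennial ice/snow, and emergent
#' herbaceous wetlands).
#'
#' @param ancillary a [ClassRaster-class] (for the uninhabited code).
#' @param zeroClasses integer codes preset to zero density.
#' @return named numeric vector of densities.
#' @export
defaultPresets <- function(ancillary, zeroClasses = integer()) {
  codes <- zeroClasses
  if (!is.na(ancillary@uninhabitedCode))
    codes <- c(codes, ancillary@uninhabitedCode)
  stats::setNames(rep(0, length(codes)), as.character(codes))
}

#' Run IDM over processing zones
#'
#' Representative densities are estimated independently within each
#' (possibly merged) zone, populations are allocated per unit, and the
#' per-cell densities are mosaicked into one seamless raster. Zones are
#' merged with `mergeMap` (e.g., `c(RI = "MA", DC = "MD")`); a single-zone
#' run corresponds to a national analysis.
#'
#' @param units prepared [SourceUnits-class] (after [mergeSmallUnits()]).
#' @param ancillary the [ClassRaster-class] ancillary raster.
#' @param presets named numeric vector of preset densities by class code;
#'   default [defaultPresets()] of the ancillary's uninhabited code.
#' @param zeroClasses additional class codes preset to zero.
#' @param overrides either a named numeric vector applied to every zone or
#'   a named list of such vectors keyed by (merged) zone id.
#' @param criteria a [SamplingCriteria-class].
#' @param mergeMap named character vector mapping zone id to the zone it is
#'   processed with.
#' @return an [IdmRun-class].
#' @export
runZones <- function(units, ancillary,
                     presets = NULL, zeroClasses = integer(),
                     overrides = list(),
                     criteria = SamplingCriteria(),
                     mergeMap = character()) {
  d <- units@data
  if (any(is.na(d$zoneId) | !nzchar(d$zoneId)))
    stopData("every unit must be assigned to a zone")
  if (is.null(presets))
    presets <- defaultPresets(ancillary, zeroClasses)
  else if (length(zeroClasses))
    presets <- c(presets,
                 stats::setNames(rep(0, length(zeroClasses)),
                                 as.character(zeroClasses)))
  ur <- rasterizeSourceUnits(units, ancillary@grid, checkMerged = FALSE)
  targets <- tabulateTargetUnits(ur, ancillary)

  effZone <- d$zoneId
  hit <- effZone %in% names(mergeMap)
  effZone[hit] <- mergeMap[effZone[hit]]
  zoneOfUnit <- stats::setNames(effZone, as.character(d$unitId))
  popOfUnit <- stats::setNames(d$population, as.character(d$unitId))

  targets$zoneId <- zoneOfUnit[as.character(targets$unitId)]
  tables <- list()
  targets$allocated <- NA_real_
  for (z in unique(effZone)) {
    zt <- targets[!is.na(targets$zoneId) & targets$zoneId == z, ]
    if (!nrow(zt)) next
    zOverrides <- if (is.list(overrides)) overrides[[z]] %||% numeric()
    else overrides
    tab <- buildDensityTable(zt, popOfUnit, presets = presets,
                             overrides = zOverrides, criteria = criteria,
                             zoneId = z)
    tables[[z]] <- tab
    dens <- stats::setNames(tab$density, as.character(tab$classCode))
    for (uid in unique(zt$unitId)) {
      rows <- which(targets$unitId == uid)
      targets$allocated[rows] <- allocatePopulation(
        popOfUnit[[as.character(uid)]],
        targets$cells[rows],
        dens[as.character(targets$classCode[rows])])
    }
  }
  cd <- computeDensity(targets, ur, ancillary)

  # bookkeeping
  allocByUnit <- tapply(targets$allocated, targets$unitId, sum)
  represented <- as.integer(names(allocByUnit))
  unalloc <- d$unitId[d$population > 0 & !(d$unitId %in% represented)]
  unallocPop <- sum(d$population[d$unitId %in% unalloc])
  pycno <- abs(allocByUnit - popOfUnit[names(allocByUnit)]) /
    pmax(1, popOfUnit[names(allocByUnit)])
  dt <- do.call(rbind, tables)
  rownames(dt) <- NULL
  summary <- list(
    nUnits = nrow(d),
    totalPopulation = sum(d$population),
    allocatedPopulation = sum(targets$allocated),
    unallocatablePopulation = unallocPop,
    unallocatableIds = unalloc,
    maxPycnophylacticError = if (length(pycno)) max(pycno) else 0,
    provenance = table(dt$method),
    perZonePopulation = tapply(
      d$population[d$unitId %in% represented],
      effZone[d$unitId %in% represented], sum))
  new("IdmRun", density = cd$raster, densityTables = dt,
      targets = cd$targets, unitRaster = ur, ancillary = ancillary,
      summary = summary)
}
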