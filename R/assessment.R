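#' @include zones.R
NULL

# Scale-up cross-validation: block-level allocations are exact by
# construction (pycnophylactic), so the density tables are validated by
# disaggregating the coarser tract level with block-derived densities and
# scoring the recovered block populations.

#' Aggregate blocks to tracts
#'
#' One unit per tract: geometry is the dissolved blocks, population the
#' exact sum of block populations. The tract id becomes the unit key;
#' county/state/zone identifiers are carried through (they are constant
#' within a tract).
#'
#' @param blocks a [SourceUnits-class].
#' @return a [SourceUnits-class] at tract level; `data$blockIds` lists the
#'   member block ids per tract.
#' @export
aggregateToTracts <- function(blocks) {
  d <- blocks@data
  if (any(is.na(d$tractId) | !nzchar(d$tractId)))
    stopData("every block needs a tract id")
  tracts <- sort(unique(d$tractId))
  geoms <- vector("list", length(tracts))
  rows <- vector("list", length(tracts))
  for (i in seq_along(tracts)) {
    sel <- which(d$tractId == tracts[i])
    geoms[[i]] <- geomUnionAll(blocks@geoms[sel])
    rows[[i]] <- data.frame(
      unitId = i,
      population = sum(d$population[sel]),
      tractId = tracts[i],
      countyId = d$countyId[sel[1L]],
      stateId = d$stateId[sel[1L]],
      zoneId = d$zoneId[sel[1L]])
  }
  out <- SourceUnits(do.call(rbind, rows), geoms, crs = blocks@crs)
  out@data$blockIds <- I(lapply(tracts, function(tr)
    d$unitId[d$tractId == tr]))
  out
}

#' Disaggregate tracts with block-derived densities
#'
#' Applies the allocator to tracts as source units, using the block-run
#' density table as presets for every class (no resampling at tract
#' level), then recovers a block-level estimate by summing the density
#' raster over each block's cells. Population is conserved at tract level.
#'
#' The tract raster is the block raster relabelled by tract id, so the two
#' levels are exactly nested cell-for-cell.
#'
#' @param blocks block-level [SourceUnits-class].
#' @param blockRaster the block [UnitRaster-class].
#' @param ancillary the [ClassRaster-class].
#' @param densityTable block-run density table (single zone) or a density
#'   vector named by class code.
#' @return list: `estimates` data.frame (`unitId`, `actual`, `estimated`,
#'   plus admin ids), `run` the tract-level [IdmRun-class].
#' @export
disaggregateWithPresets <- function(blocks, blockRaster, ancillary,
                                    densityTable) {
  d <- blocks@data
  dens <- if (is.data.frame(densityTable))
    stats::setNames(densityTable$density,
                    as.character(densityTable$classCode))
  else densityTable
  presentClasses <- unique(ancillary@codes[
    ancillary@codes != ancillary@grid@nodata])
  missing <- setdiff(as.character(presentClasses), names(dens))
  if (length(missing))
    stopData("density table lacks class(es): %s",
             paste(missing, collapse = ", "))

  tracts <- aggregateToTracts(blocks)
  td <- tracts@data
  # relabel block raster by tract
  tractIndex <- stats::setNames(td$unitId, td$tractId)
  blockTract <- stats::setNames(
    tractIndex[d$tractId], as.character(d$unitId))
  ids <- blockRaster@unitIds
  g <- blockRaster@grid
  valid <- ids != g@nodata
  tr <- ids
  tr[valid] <- as.integer(blockTract[as.character(ids[valid])])
  tractRaster <- UnitRaster(tr, g)

  targets <- tabulateTargetUnits(tractRaster, ancillary)
  popOfTract <- stats::setNames(td$population, as.character(td$unitId))
  targets$allocated <- NA_real_
  for (uid in unique(targets$unitId)) {
    rows <- which(targets$unitId == uid)
    targets$allocated[rows] <- allocatePopulation(
      popOfTract[[as.character(uid)]],
      targets$cells[rows],
      dens[as.character(targets$classCode[rows])])
  }
  cd <- computeDensity(targets, tractRaster, ancillary)

  # block-level estimates: sum density raster over each block's cells
  rasterVec <- as.vector(cd$raster)
  blockVec <- as.vector(ids)
  ok <- valid & !is.na(rasterVec)
  sums <- tapply(rasterVec[as.vector(ok)], blockVec[as.vector(ok)], sum)
  est <- stats::setNames(rep(0, nrow(d)), as.character(d$unitId))
  est[names(sums)] <- sums
  flagged <- d$unitId[d$population > 0 & !(as.character(d$unitId) %in%
                                             names(sums))]
  if (length(flagged))
    message(sprintf("block(s) with no estimated density: %s",
                    paste(flagged, collapse = ", ")))
  tab <- stats::setNames(dens[as.character(sort(unique(targets$classCode)))],
                         as.character(sort(unique(targets$classCode))))
  densityTableOut <- data.frame(zoneId = "tract-run",
                                classCode = as.integer(names(tab)),
                                density = as.numeric(tab),
                                method = "preset",
                                nSampleBlocks = NA_integer_,
                                sampledPop = NA_real_,
                                sampledCells = NA_real_)
  run <- new("IdmRun", density = cd$raster, densityTables = densityTableOut,
             targets = cd$targets, unitRaster = tractRaster,
             ancillary = ancillary,
             summary = list(
               nUnits = nrow(td),
               totalPopulation = sum(td$population),
               allocatedPopulation = sum(targets$allocated, na.rm = TRUE),
               unallocatablePopulation = 0,
               unallocatableIds = integer(),
               maxPycnophylacticError = {
                 byTract <- tapply(targets$allocated, targets$unitId, sum)
                 e <- abs(byTract - popOfTract[names(byTract)]) /
                   pmax(1, popOfTract[names(byTract)])
                 if (length(e)) max(e) else 0
               },
               provenance = table(densityTableOut$method)))
  list(estimates = data.frame(unitId = d$unitId,
                              actual = d$population,
                              estimated = as.numeric(est),
                              tractId = d$tractId,
                              countyId = d$countyId,
                              stateId = d$stateId,
                              stringsAsFactors = FALSE),
       run = run)
}

.metricsFor <- function(actual, estimated) {
  n <- length(actual)
  err <- actual - estimated
  mae <- sum(abs(err)) / n
  rmse <- sqrt(sum(err^2) / n)
  ybar <- mean(actual)
  nrmse <- if (ybar > 0) rmse / ybar else NA_real_
  data.frame(n = n, MAE = mae, RMSE = rmse, meanPop = ybar, NRMSE = nrmse)
}

#' Error metrics per summary unit
#'
#' Pooled MAE, RMSE, and NRMSE (RMSE normalized by the mean source-unit
#' population) per state, per county, and domain-wide. NRMSE is reported
#' missing (not infinite) where the mean population is zero.
#'
#' @param actual,estimated aligned numeric vectors of block populations.
#' @param stateId,countyId summary-unit assignments aligned to the blocks.
#' @return data.frame with `level`, `summaryUnit`, `n`, `MAE`, `RMSE`,
#'   `meanPop`, `NRMSE`.
#' @export
computeErrorMetrics <- function(actual, estimated,
                                stateId = rep("all", length(actual)),
                                countyId = rep("all", length(actual))) {
  if (length(actual) != length(estimated))
    stopData("actual and estimated must have equal length")
  out <- list()
  out[["domain"]] <- cbind(level = "domain", summaryUnit = "all",
                           .metricsFor(actual, estimated))
  for (s in sort(unique(stateId))) {
    sel <- stateId == s
    out[[paste0("state.", s)]] <- cbind(level = "state", summaryUnit = s,
                                        .metricsFor(actual[sel],
                                                    estimated[sel]))
  }
  for (co in sort(unique(countyId))) {
    sel <- countyId == co
    out[[paste0("county.", co)]] <- cbind(level = "county",
                                          summaryUnit = co,
                                          .metricsFor(actual[sel],
                                                      estimated[sel]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare two uninhabited-area specifications
#'
#' Per-summary-unit metric deltas, run B minus run A; negative values mean
#' B improves on A.
#'
#' @param metricsA,metricsB outputs of [computeErrorMetrics()] on the same
#'   blocks and summary units.
#' @return data.frame of joined metrics with `dMAE`, `dRMSE`, `dNRMSE`.
#' @export
compareSpecifications <- function(metricsA, metricsB) {
  key <- function(m) paste(m$level, m$summaryUnit)
  if (!identical(sort(key(metricsA)), sort(key(metricsB))))
    stopData("runs do not share summary units")
  b <- metricsB[match(key(metricsA), key(metricsB)), ]
  if (!identical(metricsA$n, b$n))
    stopData("mismatched block sets between runs")
  data.frame(level = metricsA$level, summaryUnit = metricsA$summaryUnit,
             n = metricsA$n,
             MAE_a = metricsA$MAE, MAE_b = b$MAE, dMAE = b$MAE - metricsA$MAE,
             RMSE_a = metricsA$RMSE, RMSE_b = b$RMSE,
             dRMSE = b$RMSE - metricsA$RMSE,
             NRMSE_a = metricsA$NRMSE, NRMSE_b = b$NRMSE,
             dNRMSE = b$NRMSE - metricsA$NRMSE)
}
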