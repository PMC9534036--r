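#' @include worked-example.R
NULL

# Orchestration: a single YAML config drives the stages (simulate ->
# build-uninhabited -> build-ancillary -> prep-units -> run-idm ->
# assess), each writing its outputs plus a JSON manifest with the config
# hash so any stage can be reproduced from its manifest. Logging goes to
# standard error via message().

#' Read and validate a run configuration
#'
#' @param path YAML config path.
#' @return validated config list (class `runConfig`).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stopConfig("config file '%s' does not exist", path)
  cfg <- yaml::read_yaml(path)
  cfg$configPath <- normalizePath(path)
  cfg$configHash <- unname(tools::md5sum(path))
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    slope = th$slope %||% 25,
    mixedUse = th$mixed_use %||% th$mixedUse %||% 0.90,
    total = th$total %||% 0.99)
  if (cfg$thresholds$mixedUse <= 0 || cfg$thresholds$mixedUse > 1 ||
      cfg$thresholds$total <= 0 || cfg$thresholds$total > 1)
    stopConfig("coverage thresholds must be in (0, 1]")
  if (cfg$thresholds$slope < 0)
    stopConfig("slope threshold must be non-negative")
  cr <- cfg$criteria %||% list()
  cfg$criteria <- SamplingCriteria(
    coverageThreshold = cr$coverage_threshold %||% 0.95,
    minCells = cr$min_cells %||% 2L,
    minSamples = cr$min_samples %||% 3L)
  cfg$seed <- cfg$seed %||% 1L
  cfg$outputDir <- cfg$output_dir %||% cfg$outputDir %||% "."
  for (p in unlist(cfg$paths))
    if (!is.null(p) && !file.exists(p))
      stopConfig("configured input '%s' does not exist", p)
  class(cfg) <- "runConfig"
  cfg
}

.writeManifest <- function(cfg, command, outputs, extra = list()) {
  manifest <- c(list(command = command,
                     configHash = cfg$configHash,
                     seed = cfg$seed,
                     outputs = outputs), extra)
  path <- file.path(cfg$outputDir,
                    paste0("manifest-", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.ensureOutDir <- function(cfg) {
  if (!dir.exists(cfg$outputDir))
    dir.create(cfg$outputDir, recursive = TRUE)
}

#' Simulate a synthetic study area
#'
#' Writes the landscape and (optional) slope rasters, the block layer,
#' and the per-cell truth densities for the scenario configured under
#' `simulate:` in the config (fields mirror [syntheticScenario()]).
#'
#' @param cfg a [readRunConfig()] result.
#' @return list of output paths, invisibly.
#' @export
cmdSimulate <- function(cfg) {
  .ensureOutDir(cfg)
  sim <- cfg$simulate %||% list()
  args <- list(seed = cfg$seed)
  for (nm in c("nRows", "nCols", "cellSize", "blockDim", "nPatches",
               "homogeneousPerClass", "subPixelBlocks", "subPixelPop",
               "noise", "slopeFraction", "tractDim", "nZones"))
    if (!is.null(sim[[nm]])) args[[nm]] <- sim[[nm]]
  if (!is.null(sim$classCodes)) {
    args$classCodes <- as.integer(sim$classCodes)
    args$classLabels <- sim$classLabels %||% paste0("class", sim$classCodes)
    args$trueDensities <- stats::setNames(as.numeric(sim$trueDensities),
                                          as.character(sim$classCodes))
  }
  scn <- do.call(syntheticScenario, args)
  bundle <- generateScenario(scn)
  out <- list(
    landscape = file.path(cfg$outputDir, "landscape.asc"),
    blocks = file.path(cfg$outputDir, "blocks.geojson"),
    truth = file.path(cfg$outputDir, "truth-density.asc"))
  writeClassRaster(bundle$landscape, out$landscape)
  writeFeatures(bundle$blocks, out$blocks)
  writeDensityRaster(bundle$truthDensity, bundle$grid, out$truth)
  if (!is.null(bundle$slope)) {
    out$slope <- file.path(cfg$outputDir, "slope.asc")
    writeDensityRaster(bundle$slope@percentSlope, bundle$grid, out$slope)
  }
  .writeManifest(cfg, "simulate", out,
                 list(nBlocks = length(bundle$blocks),
                      totalPopulation = sum(bundle$blocks@data$population)))
  message(sprintf("simulated %d blocks, population %g",
                  length(bundle$blocks),
                  sum(bundle$blocks@data$population)))
  invisible(out)
}

#' Build the uninhabited feature layer
#'
#' Reads the configured category-tagged layers, applies the buffer /
#' rail-yard / residential-clip / block-coverage pipeline, and writes the
#' dissolved layer. The manifest records how many blocks triggered each
#' exclusion rule.
#'
#' @param cfg a [readRunConfig()] result.
#' @return path of the written layer, invisibly.
#' @export
cmdBuildUninhabited <- function(cfg) {
  .ensureOutDir(cfg)
  outPath <- file.path(cfg$outputDir, "uninhabited.geojson")
  layersCfg <- cfg$uninhabitedLayers %||% list()
  if (!length(layersCfg)) {
    warning("no uninhabited layers configured; writing empty layer")
    writeFeatures(FeatureSet(list(), data.frame(category = character()),
                             crs = .defaultCRS()), outPath)
    .writeManifest(cfg, "build-uninhabited", list(uninhabited = outPath),
                   list(ruleCounts = list(mixedUseExclusions = 0,
                                          totalExclusions = 0)))
    return(invisible(outPath))
  }
  blocks <- readSourceUnits(cfg$paths$blocks,
                            columns = cfg$columns %||% list())
  layers <- list()
  cats <- list()
  for (lc in layersCfg) {
    kind <- lc$kind %||% "polygon"
    layers[[lc$name]] <- readFeatures(lc$path, geomType = kind,
                                      crs = blocks@crs)
    cats[[lc$name]] <- featureCategory(lc$name, kind,
                                       bufferM = lc$buffer_m %||% 0,
                                       mixedUse = lc$mixed_use %||% FALSE)
  }
  parcels <- if (!is.null(cfg$paths$parcels))
    readFeatures(cfg$paths$parcels, crs = blocks@crs) else NULL
  layer <- buildUninhabitedLayer(layers, do.call(rbind, cats), blocks,
                                 parcels = parcels,
                                 mixedUseThreshold = cfg$thresholds$mixedUse,
                                 totalThreshold = cfg$thresholds$total)
  writeFeatures(layer, outPath)
  counts <- attr(layer, "ruleCounts")
  .writeManifest(cfg, "build-uninhabited", list(uninhabited = outPath),
                 list(ruleCounts = as.list(counts)))
  message(sprintf("uninhabited layer written; exclusions: mixed-use %d, total %d",
                  counts[["mixedUseExclusions"]],
                  counts[["totalExclusions"]]))
  invisible(outPath)
}

#' Build the ancillary raster
#'
#' Reclassifies the land-cover raster with the uninhabited layer, any
#' extra masks, and the slope threshold; writes the ancillary raster and
#' a codebook CSV (code, label, preset density if any).
#'
#' @param cfg a [readRunConfig()] result.
#' @return list of output paths, invisibly.
#' @export
cmdBuildAncillary <- function(cfg) {
  .ensureOutDir(cfg)
  landcover <- readClassRaster(cfg$paths$landcover)
  uninhabited <- if (!is.null(cfg$paths$uninhabited))
    readFeatures(cfg$paths$uninhabited, crs = landcover@grid@crs) else NULL
  slope <- if (!is.null(cfg$paths$slope)) {
    s <- readDensityRaster(cfg$paths$slope)
    SlopeRaster(s$values, landcover@grid)
  } else NULL
  anc <- reclassifyAncillary(landcover, uninhabited, slope = slope,
                             slopeThreshold = cfg$thresholds$slope,
                             uninhabitedCode = cfg$uninhabitedCode %||% NULL)
  out <- list(ancillary = file.path(cfg$outputDir, "ancillary.asc"),
              codebook = file.path(cfg$outputDir, "codebook.csv"))
  writeClassRaster(anc, out$ancillary)
  presets <- cfg$presets %||% list()
  cb <- data.frame(code = as.integer(names(anc@codebook)),
                   label = unname(anc@codebook))
  cb$presetDensity <- vapply(as.character(cb$code), function(k) {
    if (!is.null(presets[[k]])) as.numeric(presets[[k]])
    else if (k == as.character(anc@uninhabitedCode)) 0
    else NA_real_
  }, numeric(1))
  utils::write.csv(cb, out$codebook, row.names = FALSE)
  delta <- summarizeReclassification(landcover, anc)
  .writeManifest(cfg, "build-ancillary", out,
                 list(cellsReclassified = attr(delta, "total"),
                      uninhabitedCode = anc@uninhabitedCode))
  invisible(out)
}

#' Prepare source units
#'
#' Reads the block layer, merges populated sub-pixel blocks into
#' qualifying neighbors, and writes the prepared units.
#'
#' @param cfg a [readRunConfig()] result.
#' @return path of the prepared layer, invisibly.
#' @export
cmdPrepUnits <- function(cfg) {
  .ensureOutDir(cfg)
  blocks <- readSourceUnits(cfg$paths$blocks,
                            columns = cfg$columns %||% list())
  grid <- readClassRaster(cfg$paths$landcover)@grid
  before <- nrow(blocks@data)
  merged <- mergeSmallUnits(blocks, grid)
  outPath <- file.path(cfg$outputDir, "units.geojson")
  writeFeatures(merged, outPath)
  .writeManifest(cfg, "prep-units", list(units = outPath),
                 list(unitsBefore = before, unitsAfter = nrow(merged@data),
                      unallocatableIds = attr(merged, "unallocatableIds")))
  invisible(outPath)
}

#' Run the dasymetric allocation
#'
#' Executes the full chain on prepared units and the ancillary raster:
#' per-zone density estimation, allocation, density raster, and a summary
#' JSON reporting the pycnophylactic check, unallocatable population, and
#' the per-class provenance tally.
#'
#' @param cfg a [readRunConfig()] result.
#' @return the [IdmRun-class], invisibly.
#' @export
cmdRunIdm <- function(cfg) {
  .ensureOutDir(cfg)
  units <- readSourceUnits(file.path(cfg$outputDir, "units.geojson"))
  anc <- readClassRaster(file.path(cfg$outputDir, "ancillary.asc"))
  # recover the uninhabited code from the codebook
  cb <- utils::read.csv(file.path(cfg$outputDir, "codebook.csv"))
  uCode <- cb$code[cb$label == "uninhabited"]
  if (length(uCode))
    anc <- ClassRaster(anc@codes, anc@grid,
                       codebook = stats::setNames(cb$label,
                                                  as.character(cb$code)),
                       uninhabitedCode = uCode[1L])
  presets <- cfg$presets %||% list()
  presetVec <- stats::setNames(as.numeric(unlist(presets)), names(presets))
  overrides <- cfg$overrides %||% list()
  overrideArg <- if (length(overrides) &&
                     all(vapply(overrides, is.list, logical(1))))
    lapply(overrides, function(o)
      stats::setNames(as.numeric(unlist(o)), names(o)))
  else stats::setNames(as.numeric(unlist(overrides)), names(overrides))
  mergeMap <- unlist(cfg$zoneMerge %||% list())
  run <- runZones(units, anc,
                  presets = if (length(presetVec)) presetVec else NULL,
                  zeroClasses = as.integer(cfg$zeroClasses %||% integer()),
                  overrides = overrideArg,
                  criteria = cfg$criteria,
                  mergeMap = if (length(mergeMap)) mergeMap else character())
  out <- list(density = file.path(cfg$outputDir, "density.asc"),
              densityTable = file.path(cfg$outputDir, "density-table.csv"),
              summary = file.path(cfg$outputDir, "run-summary.json"))
  writeDensityRaster(run@density, anc@grid, out$density)
  dt <- run@densityTables
  dt$label <- anc@codebook[as.character(dt$classCode)]
  utils::write.csv(dt, out$densityTable, row.names = FALSE)
  s <- run@summary
  jsonlite::write_json(list(
    nUnits = s$nUnits,
    totalPopulation = s$totalPopulation,
    allocatedPopulation = s$allocatedPopulation,
    unallocatablePopulation = s$unallocatablePopulation,
    maxPycnophylacticError = s$maxPycnophylacticError,
    provenance = as.list(s$provenance)),
    out$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeManifest(cfg, "run-idm", out,
                 list(unallocatablePopulation = s$unallocatablePopulation))
  message(sprintf("unallocatable population: %g", s$unallocatablePopulation))
  if (s$unallocatablePopulation > 0)
    warning(sprintf("unallocatable population: %g",
                    s$unallocatablePopulation))
  invisible(run)
}

#' Run the scale-up assessment
#'
#' Aggregates blocks to tracts, disaggregates with the block-run density
#' table as presets, and writes MAE/RMSE/NRMSE per state, county, and
#' domain. With `cfg$paths$ancillaryBaseline` set, also compares the two
#' uninhabited specifications.
#'
#' @param cfg a [readRunConfig()] result.
#' @return the metrics data.frame, invisibly.
#' @export
cmdAssess <- function(cfg) {
  .ensureOutDir(cfg)
  units <- readSourceUnits(file.path(cfg$outputDir, "units.geojson"))
  anc <- readClassRaster(file.path(cfg$outputDir, "ancillary.asc"))
  dtPath <- file.path(cfg$outputDir, "density-table.csv")
  if (!file.exists(dtPath))
    stopConfig("missing density table '%s'; run the allocation first",
               dtPath)
  dt <- utils::read.csv(dtPath)
  ur <- rasterizeSourceUnits(units, anc@grid, checkMerged = FALSE)
  res <- disaggregateWithPresets(units, ur, anc, dt)
  metrics <- computeErrorMetrics(res$estimates$actual,
                                 res$estimates$estimated,
                                 res$estimates$stateId,
                                 res$estimates$countyId)
  outPath <- file.path(cfg$outputDir, "assessment.csv")
  utils::write.csv(metrics, outPath, row.names = FALSE)
  outputs <- list(assessment = outPath)
  if (!is.null(cfg$paths$ancillaryBaseline)) {
    ancB <- readClassRaster(cfg$paths$ancillaryBaseline)
    dtB <- dt[!(dt$classCode %in% anc@uninhabitedCode), ]
    resB <- disaggregateWithPresets(units, ur, ancB, dtB)
    metricsB <- computeErrorMetrics(resB$estimates$actual,
                                    resB$estimates$estimated,
                                    resB$estimates$stateId,
                                    resB$estimates$countyId)
    cmp <- compareSpecifications(metricsB, metrics)
    outputs$comparison <- file.path(cfg$outputDir,
                                    "specification-comparison.csv")
    utils::write.csv(cmp, outputs$comparison, row.names = FALSE)
  }
  .writeManifest(cfg, "assess", outputs,
                 list(domainMAE = metrics$MAE[metrics$level == "domain"]))
  invisible(metrics)
}
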