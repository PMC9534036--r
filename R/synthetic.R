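#' @include assessment.R
NULL

# Self-contained synthetic landscapes with known ground truth. The truth
# model mirrors the estimator's own assumption -- class-homogeneous density
# within blocks -- so parameter recovery is well-defined: each cell carries
# the true density of its class (zero inside uninhabited-truth polygons),
# and block populations are the rounded (or Poisson-drawn) cell sums.
#
# Draw order under the scenario seed is fixed and documented: landscape
# patches (seed + 1), slope field (seed + 2), block roles (seed + 3),
# populations (seed + 4). Identical seed + spec => identical outputs.

#' Describe a synthetic scenario
#'
#' @param seed integer seed governing all stochastic draws.
#' @param nRows,nCols grid size in cells.
#' @param cellSize cell edge length (default 30 m).
#' @param classCodes integer ancillary codes, land-cover style.
#' @param classLabels labels for the codebook.
#' @param trueDensities named persons-per-cell truth, names = class codes.
#' @param zeroClasses codes whose density is preset to zero in estimation
#'   (e.g., open water).
#' @param blockDim c(block rows, block cols) of the rectangular block
#'   tessellation.
#' @param nPatches number of contiguous class patches in the mosaic.
#' @param homogeneousPerClass how many blocks per class are painted fully
#'   single-class so the sampler can use them (0 = none).
#' @param subPixelBlocks number of populated blocks too small to own a
#'   cell center (exercises the merge step).
#' @param subPixelPop population given to each sub-pixel block.
#' @param noise `"deterministic"` (y_b = round of the truth mean) or
#'   `"poisson"` (y_b ~ Poisson(mean)).
#' @param slopeFraction fraction of cells whose slope exceeds 25%.
#' @param tractDim c(rows, cols) of blocks grouped into one tract.
#' @param nZones number of vertical zone bands (states).
#' @param uninhabitedTruth list of multipolygons where the true density is
#'   zero regardless of class.
#' @return a `syntheticScenario` list.
#' @export
syntheticScenario <- function(seed = 1L,
                              nRows = 60L, nCols = 60L, cellSize = 30,
                              classCodes = c(11L, 21L, 22L, 41L, 52L),
                              classLabels = c("open water",
                                              "developed, low intensity",
                                              "developed, medium intensity",
                                              "evergreen forest",
                                              "shrub/scrub"),
                              trueDensities = c(`11` = 0, `21` = 2,
                                                `22` = 5, `41` = 0.1,
                                                `52` = 0.05),
                              zeroClasses = 11L,
                              blockDim = c(6L, 6L),
                              nPatches = 12L,
                              homogeneousPerClass = 3L,
                              subPixelBlocks = 0L,
                              subPixelPop = 5,
                              noise = c("deterministic", "poisson"),
                              slopeFraction = 0,
                              tractDim = c(2L, 2L),
                              nZones = 1L,
                              uninhabitedTruth = list()) {
  noise <- match.arg(noise)
  if (any(trueDensities < 0))
    stopConfig("true densities must be non-negative")
  if (length(classLabels) != length(classCodes))
    stopConfig("one label per class code required")
  if (nPatches > nRows * nCols)
    stopConfig("patch spec infeasible for grid size")
  if (prod(blockDim) > nRows * nCols)
    stopConfig("tessellation infeasible: more blocks than cells")
  structure(list(seed = as.integer(seed), nRows = as.integer(nRows),
                 nCols = as.integer(nCols), cellSize = cellSize,
                 classCodes = as.integer(classCodes),
                 classLabels = classLabels,
                 trueDensities = trueDensities,
                 zeroClasses = as.integer(zeroClasses),
                 blockDim = as.integer(blockDim),
                 nPatches = as.integer(nPatches),
                 homogeneousPerClass = as.integer(homogeneousPerClass),
                 subPixelBlocks = as.integer(subPixelBlocks),
                 subPixelPop = subPixelPop,
                 noise = noise, slopeFraction = slopeFraction,
                 tractDim = as.integer(tractDim),
                 nZones = as.integer(nZones),
                 uninhabitedTruth = uninhabitedTruth),
            class = "syntheticScenario")
}

.scnGrid <- function(scn) {
  GridSpec(scn$cellSize, scn$nRows, scn$nCols,
           originX = 0, originY = scn$nRows * scn$cellSize)
}

# integer breakpoints splitting n cells into k near-equal runs
.splitBreaks <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  cumsum(c(0L, sizes))
}

#' Generate the class mosaic and slope field
#'
#' Contiguous patches via nearest-seed (Voronoi) growth over cell centers;
#' every class occurs at least once. The optional slope field gives the
#' requested fraction of cells a slope above 25% (draws at seed + 1 and
#' seed + 2).
#'
#' @param scn a [syntheticScenario()].
#' @return list with `landscape` ([ClassRaster-class]) and `slope`
#'   ([SlopeRaster-class] or `NULL`).
#' @export
generateLandscape <- function(scn) {
  grid <- .scnGrid(scn)
  set.seed(scn$seed + 1L)
  n <- scn$nRows * scn$nCols
  seeds <- sample.int(n, scn$nPatches)
  seedRow <- (seeds - 1L) %% scn$nRows + 1L
  seedCol <- (seeds - 1L) %/% scn$nRows + 1L
  patchClass <- rep_len(scn$classCodes, scn$nPatches)
  rows <- rep(seq_len(scn$nRows), times = scn$nCols)
  cols <- rep(seq_len(scn$nCols), each = scn$nRows)
  nearest <- integer(n)
  best <- rep(Inf, n)
  for (k in seq_len(scn$nPatches)) {
    d2 <- (rows - seedRow[k])^2 + (cols - seedCol[k])^2
    better <- d2 < best
    nearest[better] <- k
    best[better] <- d2[better]
  }
  codes <- matrix(patchClass[nearest], scn$nRows, scn$nCols)
  slope <- NULL
  if (scn$slopeFraction > 0) {
    set.seed(scn$seed + 2L)
    steep <- stats::runif(n) < scn$slopeFraction
    s <- stats::runif(n, 0, 24)
    s[steep] <- stats::runif(sum(steep), 26, 60)
    slope <- SlopeRaster(matrix(s, scn$nRows, scn$nCols), grid)
  }
  cb <- stats::setNames(scn$classLabels, as.character(scn$classCodes))
  list(landscape = ClassRaster(codes, grid, codebook = cb), slope = slope)
}

#' Generate the block tessellation
#'
#' Space-filling rectangular blocks aligned to cell boundaries (so every
#' cell center lies strictly inside exactly one block), with nested
#' tract/county/state ids, a configurable count of fully homogeneous
#' blocks per class (painted onto the landscape), and a configurable count
#' of populated sub-pixel blocks carved out of host blocks (role draws at
#' seed + 3).
#'
#' @param scn a [syntheticScenario()].
#' @param landscape the [ClassRaster-class] from [generateLandscape()];
#'   returned repainted when homogeneous blocks are requested.
#' @return list with `blocks` ([SourceUnits-class], populations all zero),
#'   `landscape`, and `homogeneousBlocks` (named list class -> unit ids).
#' @export
generateBlocks <- function(scn, landscape) {
  grid <- landscape@grid
  cs <- grid@cellSize
  rowBreaks <- .splitBreaks(scn$nRows, scn$blockDim[1L])
  colBreaks <- .splitBreaks(scn$nCols, scn$blockDim[2L])
  nbr <- scn$blockDim[1L]
  nbc <- scn$blockDim[2L]
  nBlocks <- nbr * nbc
  geoms <- vector("list", nBlocks)
  rowsOut <- vector("list", nBlocks)
  zoneBreaks <- .splitBreaks(nbc, scn$nZones)
  for (br in seq_len(nbr)) {
    for (bc in seq_len(nbc)) {
      i <- (br - 1L) * nbc + bc
      x0 <- grid@originX + colBreaks[bc] * cs
      x1 <- grid@originX + colBreaks[bc + 1L] * cs
      yTop <- grid@originY - rowBreaks[br] * cs
      yBot <- grid@originY - rowBreaks[br + 1L] * cs
      geoms[[i]] <- geomRect(x0, yBot, x1 - x0, yTop - yBot)
      tr <- paste0("T", ceiling(br / scn$tractDim[1L]), "-",
                   ceiling(bc / scn$tractDim[2L]))
      zone <- paste0("Z", findInterval(bc - 0.5, zoneBreaks))
      county <- paste0(zone, "-C", ceiling(br / scn$tractDim[1L]))
      rowsOut[[i]] <- data.frame(unitId = i, population = 0,
                                 tractId = paste0(zone, "-", tr),
                                 countyId = county, stateId = zone,
                                 zoneId = zone)
    }
  }
  data <- do.call(rbind, rowsOut)
  set.seed(scn$seed + 3L)
  # homogeneous blocks: paint whole blocks single-class
  homo <- list()
  if (scn$homogeneousPerClass > 0L) {
    avail <- sample(seq_len(nBlocks))
    take <- 0L
    codes <- landscape@codes
    for (cls in scn$classCodes) {
      ids <- avail[take + seq_len(scn$homogeneousPerClass)]
      take <- take + scn$homogeneousPerClass
      if (any(is.na(ids)))
        stopConfig("not enough blocks for the requested homogeneous count")
      for (i in ids) {
        br <- (i - 1L) %/% nbc + 1L
        bc <- (i - 1L) %% nbc + 1L
        codes[(rowBreaks[br] + 1L):rowBreaks[br + 1L],
              (colBreaks[bc] + 1L):colBreaks[bc + 1L]] <- cls
      }
      homo[[as.character(cls)]] <- sort(ids)
    }
    landscape <- ClassRaster(codes, grid, codebook = landscape@codebook,
                             uninhabitedCode = landscape@uninhabitedCode)
  }
  # sub-pixel blocks carved from hosts
  if (scn$subPixelBlocks > 0L) {
    hosts <- sample(seq_len(nBlocks), scn$subPixelBlocks)
    for (k in seq_len(scn$subPixelBlocks)) {
      h <- hosts[k]
      bb <- geomBBox(geoms[[h]])
      side <- cs * 0.2
      tiny <- geomRect(bb["xmin"] + cs * 0.1, bb["ymax"] - cs * 0.3,
                       side, side)
      geoms[[h]] <- geomDiff(geoms[[h]], tiny)
      newId <- nBlocks + k
      geoms[[length(geoms) + 1L]] <- tiny
      data <- rbind(data, within(data[h, ], unitId <- newId))
    }
  }
  blocks <- SourceUnits(data, geoms, crs = grid@crs)
  list(blocks = blocks, landscape = landscape, homogeneousBlocks = homo)
}

# per-cell true density: class truth, zeroed inside uninhabited-truth
# polygons
.truthDensity <- function(scn, landscape) {
  grid <- landscape@grid
  dens <- matrix(0, grid@nRows, grid@nCols)
  for (cls in scn$classCodes) {
    dens[landscape@codes == cls] <- scn$trueDensities[[as.character(cls)]]
  }
  for (g in scn$uninhabitedTruth) {
    dens[rasterizeMask(g, grid)] <- 0
  }
  dens[landscape@codes == grid@nodata] <- 0
  dens
}

#' Assign block populations from the truth model
#'
#' Deterministic mode: y_b = round(sum of the per-cell true density over
#' the block's cells). Poisson mode: y_b ~ Poisson(that mean) at
#' seed + 4. Sub-pixel blocks (zero cells) receive `subPixelPop`.
#'
#' @param scn a [syntheticScenario()].
#' @param blocks [SourceUnits-class] from [generateBlocks()].
#' @param landscape the (possibly repainted) [ClassRaster-class].
#' @return the blocks with populations filled in; attribute
#'   `truthDensity` carries the per-cell truth matrix.
#' @export
assignPopulation <- function(scn, blocks, landscape) {
  grid <- landscape@grid
  dens <- .truthDensity(scn, landscape)
  ur <- rasterizeSourceUnits(blocks, grid, checkMerged = FALSE)
  ids <- as.vector(ur@unitIds)
  ok <- ids != grid@nodata
  means <- tapply(as.vector(dens)[ok], ids[ok], sum)
  mu <- stats::setNames(rep(0, nrow(blocks@data)),
                        as.character(blocks@data$unitId))
  mu[names(means)] <- means
  zeroCells <- !(as.character(blocks@data$unitId) %in% names(means))
  mu[zeroCells] <- scn$subPixelPop
  set.seed(scn$seed + 4L)
  pop <- if (scn$noise == "poisson") stats::rpois(length(mu), mu)
  else round(mu)
  blocks@data$population <- as.numeric(pop)
  attr(blocks, "truthDensity") <- dens
  blocks
}

#' Generate a complete scenario bundle
#'
#' Runs [generateLandscape()], [generateBlocks()], and
#' [assignPopulation()] in the documented draw order.
#'
#' @param scn a [syntheticScenario()].
#' @return list: `scenario`, `grid`, `landscape`, `slope`, `blocks`,
#'   `truthDensity`, `homogeneousBlocks`.
#' @export
generateScenario <- function(scn) {
  ls0 <- generateLandscape(scn)
  gb <- generateBlocks(scn, ls0$landscape)
  blocks <- assignPopulation(scn, gb$blocks, gb$landscape)
  list(scenario = scn, grid = gb$landscape@grid,
       landscape = gb$landscape, slope = ls0$slope,
       blocks = blocks, truthDensity = attr(blocks, "truthDensity"),
       homogeneousBlocks = gb$homogeneousBlocks)
}

#' A randomized small scenario
#'
#' Randomizes grid size (40-100 cells a side), class count, true
#' densities, block tessellation, noise mode, and zone count under one
#' seed; used for property-style testing of the whole pipeline.
#'
#' @param seed integer seed.
#' @return a [syntheticScenario()].
#' @export
randomScenario <- function(seed) {
  set.seed(seed)
  nRows <- sample(40:100, 1)
  nCols <- sample(40:100, 1)
  nClasses <- sample(3:6, 1)
  codes <- sort(sample(10:90, nClasses))
  dens <- round(stats::runif(nClasses, 0, 6), 3)
  dens[1L] <- 0   # one water-like preset-zero class
  blockDim <- c(sample(5:8, 1), sample(5:8, 1))  # >= 25 blocks, enough
                                                 # for 3 per class + hosts
  syntheticScenario(
    seed = seed, nRows = nRows, nCols = nCols,
    classCodes = codes,
    classLabels = paste0("class", codes),
    trueDensities = stats::setNames(dens, as.character(codes)),
    zeroClasses = codes[1L],
    blockDim = blockDim,
    nPatches = sample(8:20, 1),
    homogeneousPerClass = 3L,
    subPixelBlocks = sample(0:2, 1),
    noise = sample(c("deterministic", "poisson"), 1),
    nZones = sample(1:2, 1))
}
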