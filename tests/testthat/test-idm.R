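# the IDM estimator: tabulation, sampling, IAW, allocation, density

test_that("target units tabulate the unit-class intersection", {
  g <- testGrid(4, 4)
  u <- matrix(g@nodata, 4, 4)
  u[1:3, 1:4] <- 1L                       # 12 cells
  a <- matrix(20L, 4, 4)
  a[1:3, 1:3] <- 10L                      # 9 forest, 3 water inside unit 1
  tt <- tabulateTargetUnits(UnitRaster(u, g), ClassRaster(a, g))
  expect_equal(tt$cells[tt$unitId == 1 & tt$classCode == 10], 9)
  expect_equal(tt$cells[tt$unitId == 1 & tt$classCode == 20], 3)
  expect_equal(sum(tt$cells[tt$unitId == 1]), 12)
  # unit over all-nodata ancillary is flagged
  a2 <- matrix(g@nodata, 4, 4)
  tt2 <- tabulateTargetUnits(UnitRaster(u, g), ClassRaster(a2, g))
  expect_equal(nrow(tt2), 0)
  expect_equal(attr(tt2, "flaggedUnits"), 1L)
})

test_that("representative-block selection respects both thresholds", {
  mkTargets <- function(classCells, otherCells) {
    data.frame(unitId = rep(1L, 2), classCode = c(1L, 2L),
               cells = c(classCells, otherCells))
  }
  crit <- SamplingCriteria()
  # 96% of 25 cells -> selected
  expect_equal(selectRepresentativeBlocks(mkTargets(24, 1), 1L, crit), 1L)
  # 94% -> rejected
  expect_equal(length(selectRepresentativeBlocks(mkTargets(47, 3), 1L, crit)), 0)
  # exactly 95% -> selected (inclusive)
  expect_equal(selectRepresentativeBlocks(mkTargets(19, 1), 1L, crit), 1L)
  # 100% single cell -> rejected (area must exceed one pixel)
  one <- data.frame(unitId = 1L, classCode = 1L, cells = 1L)
  expect_equal(length(selectRepresentativeBlocks(one, 1L, crit)), 0)
  # 100% with two cells -> selected
  two <- data.frame(unitId = 1L, classCode = 1L, cells = 2L)
  expect_equal(selectRepresentativeBlocks(two, 1L, crit), 1L)
})

test_that("sampled density is the ratio of sums, not the mean of ratios", {
  expect_equal(estimateSampledDensity(c(10, 20, 30), c(10, 10, 10)), 2.0)
  expect_equal(estimateSampledDensity(c(0, 0, 0), c(10, 10, 10)), 0.0)
  # the discriminating case: mean of ratios would give 1.0
  expect_equal(estimateSampledDensity(c(10, 0), c(5, 45)), 0.2)
  # scale invariance: duplicating every block leaves the estimate unchanged
  y <- c(7, 3, 12); a <- c(4, 9, 2)
  expect_equal(estimateSampledDensity(rep(y, 2), rep(a, 2)),
               estimateSampledDensity(y, a))
})

test_that("remainders, clamping, and IAW follow the areal-weighting chain", {
  tc <- c(`11` = 5, `21` = 30, `41` = 10, `52` = 30)
  known <- c(`11` = 0, `21` = 2)
  expect_equal(computeRemainder(100, tc, known), 40)
  expect_equal(computeRemainder(100, tc[c("41", "52")], known), 100)
  expect_equal(computeRemainder(50, c(`22` = 20), c(`22` = 3)), -10)
  # areal weighting of the remainder
  expect_equal(initialUnsampledAllocation(40, c(10, 30)), c(10, 30))
  expect_equal(initialUnsampledAllocation(-5, c(10, 30)), c(0, 0))
  expect_equal(initialUnsampledAllocation(40, 25), 40)
  expect_equal(length(initialUnsampledAllocation(40, numeric())), 0)
  # IAW density: ratio of summed initial estimates to summed cells
  expect_equal(estimateIawDensity(c(40, 20), c(10, 20)), 2.0)
  expect_equal(estimateIawDensity(c(0, 0), c(10, 20)), 0)
})

test_that("density tables apply preset > sampled > IAW precedence", {
  # zone: 4 homogeneous water blocks, 3 homogeneous developed blocks,
  # 2 shrub-dominated blocks (below min_samples), plus a mixed block
  targets <- rbind(
    data.frame(unitId = 1:4, classCode = 11L, cells = 10L),
    data.frame(unitId = 5:7, classCode = 21L, cells = 10L),
    data.frame(unitId = 8:9, classCode = 52L, cells = 10L),
    data.frame(unitId = 10L, classCode = c(21L, 52L), cells = c(6L, 4L)))
  pops <- setNames(c(50, 50, 50, 50, 20, 20, 20, 3, 3, 16),
                   as.character(1:10))
  tab <- buildDensityTable(targets, pops, presets = c(`11` = 0),
                           zoneId = "Z1")
  expect_equal(nrow(tab), 3)
  # water preset to zero despite plentiful homogeneous water blocks
  expect_equal(tab$method[tab$classCode == 11], "preset")
  expect_equal(tab$density[tab$classCode == 11], 0)
  # developed sampled: 60 persons / 30 cells
  expect_equal(tab$method[tab$classCode == 21], "sampled")
  expect_equal(tab$density[tab$classCode == 21], 2.0)
  expect_equal(tab$nSampleBlocks[tab$classCode == 21], 3L)
  # shrub has only 2 representative blocks -> IAW
  expect_equal(tab$method[tab$classCode == 52], "iaw")
  # IAW oracle by hand: units 8..10 allocate their remainders to shrub
  # unit 8, 9: G = 3 (all-shrub); unit 10: G = 16 - 2*6 = 4 over 4 cells
  expect_equal(tab$density[tab$classCode == 52], (3 + 3 + 4) / 24)
  # a manual override beats the sampled value
  tab2 <- buildDensityTable(targets, pops, presets = c(`11` = 0),
                            overrides = c(`21` = 0.181), zoneId = "Z1")
  expect_equal(tab2$density[tab2$classCode == 21], 0.181)
  expect_equal(tab2$method[tab2$classCode == 21], "preset")
  # override for an absent class warns; negative density errors
  expect_warning(buildDensityTable(targets, pops,
                                   overrides = c(`99` = 1)), "absent")
  expect_error(buildDensityTable(targets, pops, presets = c(`11` = -1)),
               "non-negative")
})

test_that("allocation is pycnophylactic with the documented fallback", {
  # weighted case: densities 5.0 and 0.2 (the two-class worked pattern)
  y <- allocatePopulation(100, c(10, 50), c(5, 0.2))
  expect_equal(y, c(250 / 3, 50 / 3))
  expect_equal(sum(y), 100)
  # all densities zero: pure areal weighting, population never lost
  expect_equal(allocatePopulation(12, c(3, 1), c(0, 0)), c(9, 3))
  # zero population allocates zeros
  expect_equal(allocatePopulation(0, c(3, 1), c(5, 1)), c(0, 0))
})

test_that("per-target densities paint the raster and conserve totals", {
  g <- testGrid(4, 4)
  u <- matrix(g@nodata, 4, 4)
  u[1:3, 1:4] <- 1L
  a <- matrix(20L, 4, 4); a[1:3, 1:3] <- 10L
  ur <- UnitRaster(u, g); anc <- ClassRaster(a, g)
  tt <- tabulateTargetUnits(ur, anc)
  tt$allocated <- allocatePopulation(100, tt$cells,
                                     c(`10` = 5, `20` = 0.2)[
                                       as.character(tt$classCode)])
  cd <- computeDensity(tt, ur, anc)
  expect_equal(cd$targets$density, cd$targets$allocated / cd$targets$cells)
  expect_equal(sum(cd$raster, na.rm = TRUE), 100, tolerance = 1e-9)
  expect_true(all(is.na(cd$raster[4, ])))
})

test_that("zones are estimated independently and mosaicked seamlessly", {
  # two zone bands with different true densities for the same class
  scn <- syntheticScenario(seed = 3, nZones = 2, nRows = 40, nCols = 60,
                           classCodes = c(11L, 21L),
                           classLabels = c("water", "developed"),
                           trueDensities = c(`11` = 0, `21` = 3),
                           blockDim = c(4L, 6L), homogeneousPerClass = 6L)
  bundle <- generateScenario(scn)
  # make the eastern zone genuinely denser
  d <- unitData(bundle$blocks)
  east <- d$zoneId == "Z2"
  bundle$blocks@data$population[east] <- d$population[east] * 2
  chain <- runScenarioChain(bundle)
  dt <- densityTables(chain$run)
  d21 <- dt[dt$classCode == 21, ]
  expect_equal(nrow(d21), 2)
  expect_gt(d21$density[d21$zoneId == "Z2"],
            d21$density[d21$zoneId == "Z1"])
  # mosaic: every zone's units sum to their population
  s <- runSummary(chain$run)
  expect_lt(s$maxPycnophylacticError, 1e-6)
  # merge map: single table for the merged pair
  mergedRun <- suppressWarnings(
    runZones(chain$units, chain$ancillary, zeroClasses = 11L,
             mergeMap = c(Z2 = "Z1")))
  expect_equal(unique(densityTables(mergedRun)$zoneId), "Z1")
  # a unit with a missing zone fails loudly
  broken <- chain$units
  broken@data$zoneId[1] <- ""
  expect_error(runZones(broken, chain$ancillary), "zone")
})

test_that("allocation equals the per-cell brute-force oracle", {
  for (seed in c(2, 5, 9)) {
    bundle <- generateScenario(randomScenario(seed))
    chain <- runScenarioChain(bundle)
    run <- chain$run
    dt <- densityTables(run)
    for (z in unique(dt$zoneId)) {
      zd <- dt[dt$zoneId == z, ]
      dens <- setNames(zd$density, as.character(zd$classCode))
      ud <- unitData(chain$units)
      zoneUnits <- ud$unitId[ud$zoneId == z]
      pops <- setNames(ud$population, as.character(ud$unitId))
      oracle <- bruteForceAllocation(run@unitRaster, run@ancillary,
                                     pops, dens, unitIds = zoneUnits)
      ids <- rasterValues(run@unitRaster)
      sel <- ids %in% zoneUnits & !is.na(oracle)
      got <- densityRaster(run)[sel]
      want <- oracle[sel]
      expect_lt(max(abs(got - want) / pmax(1e-12, abs(want) + 1e-12)), 1e-9)
    }
  }
})

test_that("sampled densities recover the truth on homogeneous landscapes", {
  bundle <- generateScenario(syntheticScenario(seed = 21))
  chain <- runScenarioChain(bundle)
  dt <- densityTables(chain$run)
  truth <- bundle$scenario$trueDensities
  sampled <- dt[dt$method == "sampled", ]
  expect_gte(nrow(sampled), 3)
  counts <- .rasterCellCounts(chain$run@unitRaster)
  minA <- min(counts)
  for (i in seq_len(nrow(sampled))) {
    expect_lt(abs(sampled$density[i] -
                    truth[[as.character(sampled$classCode[i])]]),
              1 / minA)
  }
})

test_that("expanding the uninhabited mask preserves unit totals", {
  bundle <- generateScenario(syntheticScenario(seed = 13))
  chain <- runScenarioChain(bundle)
  mask <- rectSet(list(c(300, 300, 600, 600)),
                  data.frame(category = "park", mixedUse = FALSE),
                  crs = bundle$grid@crs)
  chainMasked <- runScenarioChain(bundle, uninhabited = mask)
  totals <- function(run) tapply(targetUnits(run)$allocated,
                                 targetUnits(run)$unitId, sum)
  t1 <- totals(chain$run)
  t2 <- totals(chainMasked$run)
  expect_equal(t2[names(t1)], t1, tolerance = 1e-9)
  # but the arrangement changes: masked cells carry zero density except
  # inside units that fell back to areal weighting (every density zero)
  u <- uninhabitedCode(chainMasked$ancillary)
  dt2 <- densityTables(chainMasked$run)
  dens <- setNames(dt2$density, as.character(dt2$classCode))
  tu <- targetUnits(chainMasked$run)
  weight <- tapply(tu$cells * dens[as.character(tu$classCode)],
                   tu$unitId, sum)
  weighted <- as.integer(names(weight)[weight > 0])
  masked <- rasterValues(chainMasked$ancillary) == u &
    matrix(rasterValues(chainMasked$run@unitRaster) %in% weighted,
           nrow(rasterValues(chainMasked$ancillary)))
  expect_true(all(densityRaster(chainMasked$run)[masked] == 0, na.rm = TRUE))
})
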