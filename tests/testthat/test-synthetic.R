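# the synthetic-landscape generator and its ground truth

test_that("generation is deterministic under a fixed seed", {
  a <- generateScenario(syntheticScenario(seed = 7))
  b <- generateScenario(syntheticScenario(seed = 7))
  expect_identical(rasterValues(a$landscape), rasterValues(b$landscape))
  expect_identical(unitData(a$blocks), unitData(b$blocks))
  expect_identical(a$truthDensity, b$truthDensity)
  c2 <- generateScenario(syntheticScenario(seed = 8))
  expect_false(identical(rasterValues(a$landscape),
                         rasterValues(c2$landscape)))
})

test_that("every class occurs and a single-class spec is uniform", {
  bundle <- generateScenario(syntheticScenario(seed = 2))
  present <- unique(as.vector(rasterValues(bundle$landscape)))
  expect_true(all(bundle$scenario$classCodes %in% present))
  uni <- generateScenario(syntheticScenario(
    seed = 2, classCodes = 21L, classLabels = "developed",
    trueDensities = c(`21` = 2), zeroClasses = integer(), nPatches = 4L,
    homogeneousPerClass = 0L))
  expect_true(all(rasterValues(uni$landscape) == 21L))
})

test_that("the slope field hits the requested steep fraction", {
  bundle <- generateScenario(syntheticScenario(seed = 5,
                                               slopeFraction = 0.1))
  s <- rasterValues(bundle$slope)
  frac <- mean(s > 25)
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.12)
})

test_that("requested homogeneous blocks pass the representative selector", {
  scn <- syntheticScenario(seed = 9, nRows = 72, nCols = 72,
                           classCodes = c(1L, 2L),
                           classLabels = c("A", "B"),
                           trueDensities = c(`1` = 2, `2` = 0.5),
                           zeroClasses = integer(),
                           blockDim = c(6L, 6L),
                           homogeneousPerClass = 12L)
  bundle <- generateScenario(scn)
  ur <- rasterizeSourceUnits(bundle$blocks, bundle$grid)
  targets <- tabulateTargetUnits(ur, bundle$landscape)
  reps <- selectRepresentativeBlocks(targets, 1L)
  expect_gte(length(reps), 12)
  expect_true(all(bundle$homogeneousBlocks[["1"]] %in% reps))
})

test_that("sub-pixel blocks are exactly the unrepresented ones", {
  bundle <- generateScenario(syntheticScenario(seed = 10,
                                               subPixelBlocks = 3L))
  found <- findUnrepresentedUnits(bundle$blocks, bundle$grid)
  expect_equal(length(found), 3)
  expect_true(all(found > 36))   # appended after the 6x6 tessellation
  # and each carries the configured population
  d <- unitData(bundle$blocks)
  expect_true(all(d$population[d$unitId %in% found] == 5))
})

test_that("blocks tile the grid: block cells sum to assigned cells", {
  bundle <- generateScenario(syntheticScenario(seed = 12))
  ur <- rasterizeSourceUnits(bundle$blocks, bundle$grid)
  ids <- rasterValues(ur)
  expect_equal(sum(ids != bundle$grid@nodata),
               bundle$grid@nRows * bundle$grid@nCols)
})

test_that("deterministic populations equal rounded truth sums", {
  bundle <- generateScenario(syntheticScenario(seed = 14))
  ur <- rasterizeSourceUnits(bundle$blocks, bundle$grid)
  ids <- as.vector(rasterValues(ur))
  ok <- ids != bundle$grid@nodata
  sums <- tapply(as.vector(bundle$truthDensity)[ok], ids[ok], sum)
  d <- unitData(bundle$blocks)
  for (uid in names(sums))
    expect_equal(d$population[d$unitId == as.integer(uid)],
                 round(sums[[uid]]))
  # all-zero densities produce all-zero populations
  zero <- generateScenario(syntheticScenario(
    seed = 14, trueDensities = c(`11` = 0, `21` = 0, `22` = 0,
                                 `41` = 0, `52` = 0)))
  expect_true(all(unitData(zero$blocks)$population == 0))
})

test_that("poisson populations have the right mean (CLT bound)", {
  # 1000 blocks of 4 cells at 5 persons/cell: mean block population 20
  scn <- syntheticScenario(seed = 15, nRows = 50, nCols = 80,
                           classCodes = 21L, classLabels = "developed",
                           trueDensities = c(`21` = 5),
                           zeroClasses = integer(),
                           blockDim = c(25L, 40L), nPatches = 4L,
                           homogeneousPerClass = 0L, noise = "poisson")
  bundle <- generateScenario(scn)
  pops <- unitData(bundle$blocks)$population
  expect_equal(length(pops), 1000)
  expect_lt(abs(mean(pops) - 20), 3 * sqrt(20 / 1000))
})

test_that("the worked example is fixed and internally consistent", {
  a <- workedExampleFixture()
  b <- workedExampleFixture()
  expect_identical(unitData(a$blocks), unitData(b$blocks))
  expect_identical(a$truthDensity, b$truthDensity)
  expect_equal(sum(unitData(a$blocks)$population), 1680)
  tracts <- aggregateToTracts(a$blocks)
  expect_equal(unitData(tracts)$population,
               sum(unitData(a$blocks)$population))
})
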