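# uninhabited-feature construction: buffers, rail yards, clipping,
# block-coverage rules, dissolve

test_that("bufferLines produces capsules and enforces its contract", {
  lines <- lineSet(c(0, 100), c(0, 0))
  out <- bufferLines(lines, 15)
  expect_equal(out@geomType, "polygon")
  expected <- 100 * 30 + pi * 15^2
  expect_lt(abs(geomArea(geometries(out)[[1]]) - expected) / expected, 0.01)
  expect_error(bufferLines(lines, 0), "positive")
  # zero-length line is skipped with a warning
  degenerate <- FeatureSet(list(list(list(x = c(5, 5), y = c(5, 5)))),
                           data.frame(name = "pt"), geomType = "line",
                           crs = lines@crs)
  expect_warning(out <- bufferLines(degenerate, 15), "zero-length")
  expect_equal(length(out), 0)
})

test_that("rail yards are derived by select-buffer-dissolve-erode", {
  yards <- lineSet(c(0, 1000), c(0, 0), data.frame(name = "UP YARDS A"))
  out <- deriveRailYards(yards)
  expected <- 1000 * 40 + pi * 20^2   # capsule of half-width 500 - 480
  expect_lt(abs(geomArea(geometries(out)[[1]]) - expected) / expected, 0.01)
  # case-insensitive token matching
  lower <- lineSet(c(0, 1000), c(0, 0), data.frame(name = "bn yards west"))
  expect_equal(length(deriveRailYards(lower)), 1)
  # no "YARDS" in any name -> empty set
  none <- lineSet(c(0, 1000), c(0, 0), data.frame(name = "MAIN LINE"))
  expect_equal(length(deriveRailYards(none)), 0)
  expect_error(deriveRailYards(lineSet(c(0, 1), c(0, 0),
                                       data.frame(id = 1))), "name")
})

test_that("dissolving before erosion keeps the bridged interior", {
  two <- FeatureSet(list(list(list(x = c(0, 1000), y = c(0, 0))),
                         list(list(x = c(0, 1000), y = c(900, 900)))),
                    data.frame(name = c("YARDS N", "YARDS S")),
                    geomType = "line")
  joint <- deriveRailYards(two)
  jointArea <- sum(vapply(geometries(joint), geomArea, numeric(1)))
  # oracle: erode each 500 m capsule independently and sum
  separate <- sum(vapply(two@geoms, function(paths) {
    geomArea(geomOffset(geomBufferLines(paths, 500), -480))
  }, numeric(1)))
  expect_gt(jointArea, separate)
})

test_that("residential clipping removes parcel area and drops empties", {
  features <- rectSet(list(c(0, 0, 100, 100), c(500, 500, 20, 20)),
                      data.frame(category = c("forest", "park"),
                                 mixedUse = FALSE))
  # 40% of the first feature; the second is fully covered
  parcels <- rectSet(list(c(0, 0, 40, 100), c(495, 495, 40, 40)))
  out <- clipResidential(features, parcels)
  expect_equal(length(out), 1)
  expect_equal(featureData(out)$category, "forest")
  expect_equal(geomArea(geometries(out)[[1]]), 6000)
  # no parcels -> identity
  none <- FeatureSet(list(), data.frame(), geomType = "polygon",
                     crs = features@crs)
  expect_equal(length(clipResidential(features, none)), 2)
})

test_that("mixed-use rule is strict at 90% and block-local", {
  blocks <- rectUnits(list(c(0, 0, 100, 100), c(100, 0, 100, 100)),
                      c(50, 50))
  mk <- function(w) {
    FeatureSet(list(geomRect(0, 0, w, 100)),
               data.frame(category = "mall", mixedUse = TRUE),
               geomType = "polygon", crs = blocks@crs)
  }
  # exactly 90% coverage: NOT excluded
  out <- applyBlockCoverageRules(mk(90), blocks)
  expect_equal(length(out), 1)
  expect_equal(attr(out, "mixedUseExclusions"), 0L)
  # 90.1%: excluded within the triggering block only
  spanning <- FeatureSet(list(geomRect(0, 0, 130, 100)),
                         data.frame(category = "mall", mixedUse = TRUE),
                         geomType = "polygon", crs = blocks@crs)
  out <- applyBlockCoverageRules(spanning, blocks)
  expect_equal(attr(out, "mixedUseExclusions"), 1L)
  # the part in block 2 (x 100..130) survives
  expect_equal(geomArea(geometries(out)[[1]]), 3000)
})

test_that("the 99% total rule excludes near-fully-covered blocks", {
  blocks <- rectUnits(list(c(0, 0, 100, 100)), 25)
  mk <- function(w) {
    FeatureSet(list(geomRect(0, 0, w, 100)),
               data.frame(category = "cemetery", mixedUse = FALSE),
               geomType = "polygon", crs = blocks@crs)
  }
  # 99.5% -> excluded, block stays allocatable
  out <- applyBlockCoverageRules(mk(99.5), blocks)
  expect_equal(length(out), 0)
  expect_equal(attr(out, "totalExclusions"), 1L)
  # 98% -> retained
  out <- applyBlockCoverageRules(mk(98), blocks)
  expect_equal(length(out), 1)
  # exactly 99% -> retained (strict)
  out <- applyBlockCoverageRules(mk(99), blocks)
  expect_equal(length(out), 1)
  # 99.1% -> excluded
  out <- applyBlockCoverageRules(mk(99.1), blocks)
  expect_equal(length(out), 0)
})

test_that("a 95%-covered mixed-use mall is excluded but the block remains", {
  blocks <- rectUnits(list(c(0, 0, 100, 100)), 120)
  mall <- FeatureSet(list(geomRect(0, 0, 95, 100)),
                     data.frame(category = "mall", mixedUse = TRUE),
                     geomType = "polygon", crs = blocks@crs)
  out <- applyBlockCoverageRules(mall, blocks)
  expect_equal(length(out), 0)
  expect_equal(attr(out, "mixedUseExclusions"), 1L)
  # the non-mixed-use equivalent at 95% is kept (below the 99% rule)
  cemetery <- FeatureSet(mall@geoms,
                         data.frame(category = "cemetery", mixedUse = FALSE),
                         geomType = "polygon", crs = blocks@crs)
  expect_equal(length(applyBlockCoverageRules(cemetery, blocks)), 1)
})

test_that("merging dissolves overlaps and keeps provenance labels", {
  a <- rectSet(list(c(0, 0, 100, 100)),
               data.frame(category = "park", mixedUse = FALSE))
  b <- rectSet(list(c(50, 0, 100, 100)),
               data.frame(category = "cemetery", mixedUse = FALSE))
  out <- mergeUninhabited(a, b)
  expect_equal(geomArea(geometries(out)[[1]]), 15000)
  expect_equal(featureData(out)$category, "cemetery,park")
  # disjoint inputs: area equals the sum of parts
  c2 <- rectSet(list(c(400, 400, 10, 10)),
                data.frame(category = "school", mixedUse = FALSE))
  out <- mergeUninhabited(a, c2)
  expect_equal(sum(vapply(geometries(out), geomArea, numeric(1))), 10100)
  # empty input -> empty set
  expect_equal(length(mergeUninhabited()), 0)
})

test_that("the pipeline is monotone non-increasing in area", {
  set.seed(42)
  blocks <- rectUnits(list(c(0, 0, 120, 120), c(120, 0, 120, 120)),
                      c(10, 10))
  features <- rectSet(list(c(10, 10, 100, 100), c(130, 5, 100, 110)),
                      data.frame(category = c("mall", "park"),
                                 mixedUse = c(TRUE, FALSE)))
  parcels <- rectSet(list(c(20, 20, 30, 30)))
  areaOf <- function(fs) sum(vapply(fs@geoms, geomArea, numeric(1)))
  a0 <- areaOf(features)
  clipped <- clipResidential(features, parcels)
  expect_lte(areaOf(clipped), a0)
  ruled <- applyBlockCoverageRules(clipped, blocks)
  expect_lte(areaOf(ruled), areaOf(clipped))
  # reordering features does not change the dissolved result
  m1 <- mergeUninhabited(ruled)
  m2 <- mergeUninhabited(ruled[rev(seq_len(length(ruled)))])
  expect_equal(areaOf(m1), areaOf(m2))
})
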