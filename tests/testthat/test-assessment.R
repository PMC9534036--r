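# scale-up cross-validation: aggregate, disaggregate, score

test_that("tract aggregation dissolves geometry and sums population exactly", {
  blocks <- rectUnits(list(c(0, 0, 60, 60), c(60, 0, 60, 60),
                           c(120, 0, 60, 60), c(180, 0, 60, 60),
                           c(0, 60, 120, 60), c(120, 60, 120, 60)),
                      c(120, 80, 40, 10, 30, 20))
  tracts <- aggregateToTracts(blocks)
  expect_equal(nrow(unitData(tracts)), 1)
  expect_equal(unitData(tracts)$population, 300)
  expect_equal(geomArea(geometries(tracts)[[1]]),
               sum(vapply(geometries(blocks), geomArea, numeric(1))))
  # single-block tract is the identity
  one <- rectUnits(list(c(0, 0, 60, 60)), 7)
  expect_equal(unitData(aggregateToTracts(one))$population, 7)
  # conservation across many tracts
  bundle <- generateScenario(syntheticScenario(seed = 4))
  tr <- aggregateToTracts(bundle$blocks)
  expect_equal(sum(unitData(tr)$population),
               sum(unitData(bundle$blocks)$population))
})

test_that("tracts identical to blocks reproduce populations exactly", {
  scn <- syntheticScenario(seed = 6, tractDim = c(1L, 1L))
  bundle <- generateScenario(scn)
  chain <- runScenarioChain(bundle)
  res <- disaggregateWithPresets(chain$units, chain$run@unitRaster,
                                 chain$ancillary,
                                 densityTables(chain$run))
  expect_equal(res$estimates$estimated, res$estimates$actual,
               tolerance = 1e-9)
  m <- computeErrorMetrics(res$estimates$actual, res$estimates$estimated,
                           res$estimates$stateId, res$estimates$countyId)
  expect_true(all(abs(m$MAE) < 1e-9))
  expect_true(all(abs(m$RMSE) < 1e-9))
})

test_that("tract-level disaggregation is pycnophylactic at tract level", {
  bundle <- generateScenario(syntheticScenario(seed = 8))
  chain <- runScenarioChain(bundle)
  res <- disaggregateWithPresets(chain$units, chain$run@unitRaster,
                                 chain$ancillary,
                                 densityTables(chain$run))
  est <- res$estimates
  byTract <- tapply(est$estimated, est$tractId, sum)
  actual <- tapply(est$actual, est$tractId, sum)
  expect_equal(byTract[names(actual)], actual, tolerance = 1e-9)
  # a class missing from the table is a contract error
  dt <- densityTables(chain$run)
  expect_error(disaggregateWithPresets(chain$units, chain$run@unitRaster,
                                       chain$ancillary, dt[-1, ]),
               "lacks class")
})

test_that("error metrics match hand arithmetic", {
  m <- computeErrorMetrics(c(10, 20), c(12, 16))
  dom <- m[m$level == "domain", ]
  expect_equal(dom$MAE, 3.0, tolerance = 1e-4)
  expect_equal(dom$RMSE, 3.1623, tolerance = 1e-4)
  expect_equal(dom$NRMSE, 0.2108, tolerance = 1e-4)
  # identical estimates -> zero error at every summary level
  z <- computeErrorMetrics(c(5, 7), c(5, 7))
  expect_true(all(z$MAE == 0) && all(z$RMSE == 0))
  # single block: MAE = RMSE = |e|
  s <- computeErrorMetrics(10, 14)
  expect_equal(s$MAE[1], 4)
  expect_equal(s$RMSE[1], 4)
  # zero mean population: NRMSE missing, not infinite
  zm <- computeErrorMetrics(c(0, 0), c(1, 1))
  expect_true(is.na(zm$NRMSE[1]))
  expect_false(is.infinite(zm$NRMSE[1]))
})

test_that("RMSE >= MAE and NRMSE is scale-invariant", {
  set.seed(99)
  for (i in 1:5) {
    actual <- rpois(40, 30)
    est <- actual + rnorm(40, 0, 5)
    m <- computeErrorMetrics(actual, est)
    expect_gte(m$RMSE[1] + 1e-12, m$MAE[1])
    m10 <- computeErrorMetrics(actual * 10, est * 10)
    expect_equal(m10$NRMSE[1], m$NRMSE[1], tolerance = 1e-9)
  }
})

test_that("specification comparisons are aligned and antisymmetric", {
  mA <- computeErrorMetrics(c(10, 20, 5), c(12, 16, 5),
                            c("S1", "S1", "S2"), c("C1", "C1", "C2"))
  mB <- computeErrorMetrics(c(10, 20, 5), c(11, 18, 5),
                            c("S1", "S1", "S2"), c("C1", "C1", "C2"))
  same <- compareSpecifications(mA, mA)
  expect_true(all(same$dMAE == 0))
  ab <- compareSpecifications(mA, mB)
  ba <- compareSpecifications(mB, mA)
  expect_equal(ab$dMAE, -ba$dMAE)
  expect_equal(ab$dRMSE, -ba$dRMSE)
  # mismatched summary units error
  mC <- computeErrorMetrics(c(1, 2), c(1, 2), c("S9", "S9"), c("C9", "C9"))
  expect_error(compareSpecifications(mA, mC), "summary units")
})

test_that("masking a truly uninhabited cemetery improves tract MAE", {
  wx <- runWorkedExample()
  maeBase <- wx$metricsBaseline$MAE[wx$metricsBaseline$level == "domain"]
  maeUpd <- wx$metricsUpdated$MAE[wx$metricsUpdated$level == "domain"]
  expect_lt(maeUpd, maeBase)
  expect_lt(wx$comparison$dMAE[wx$comparison$level == "domain"], 0)
})
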