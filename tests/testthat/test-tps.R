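test_that("candidate lattice matches the analytic eroded-sphere count", {
  # 15 mm sphere, 3 mm pitch, 1 mm margin: lattice points inside the
  # 6.5 mm eroded radius, counted independently
  gtv <- sphereMask(15, 1)
  cfg <- planConfig(candidatePitchMm = 3, siteMarginMm = 1)
  cand <- candidateSites(gtv, cfg)
  expect_equal(nrow(cand), latticePointsInSphere(6.5, 3))  # 33
  # all candidates lie inside the GTV
  m <- voxelData(gtv)
  expect_true(all(m[as.matrix(cand[, c("i", "j", "k")])]))
})

test_that("erosion falling empty returns the centroid as sole candidate", {
  small <- sphereMask(3, 1, marginVox = 3)
  cand <- candidateSites(small, planConfig(candidatePitchMm = 5,
                                           siteMarginMm = 2))
  expect_equal(nrow(cand), 1)
  expect_equal(unlist(cand[1, c("x_mm", "y_mm", "z_mm")]),
               c(x_mm = 0, y_mm = 0, z_mm = 0))
  expect_error(candidateSites(emptyGrid(9), planConfig()), "empty")
})

test_that("a GTV inside the single-UoT isodose needs exactly one injection", {
  gtv <- sphereMask(6, 1, marginVox = 3)
  plan <- greedyPlan(gtv)
  expect_equal(nrow(plan@injections), 1)
  expect_true(plan@feasible)
  expect_equal(plan@achievedCoverage, 1)
})

test_that("the injection cap is honored and reported honestly", {
  gtv <- sphereMask(15, 1)
  plan <- greedyPlan(gtv, planConfig(maxInjections = 1))
  expect_equal(nrow(plan@injections), 1)
  expect_false(plan@feasible)
  expect_lt(plan@achievedCoverage, 0.95)
})

test_that("greedy plans are valid, monotone and reproducible by the engine", {
  gtv <- sphereMask(12, 1)
  cfg <- planConfig()
  plan <- greedyPlan(gtv, cfg)
  inj <- plan@injections
  # volumes from the allowed set
  expect_true(all(inj$volume_ul %in% cfg$allowedVolumesUl))
  # pairwise spacing
  if (nrow(inj) > 1) {
    dmat <- as.matrix(dist(inj[, c("x_mm", "y_mm", "z_mm")]))
    expect_true(all(dmat[upper.tri(dmat)] >= cfg$minSiteSpacingMm - 1e-9))
  }
  # sites inside the GTV
  or <- voxelOrigin(gtv); sp <- voxelSpacing(gtv)
  idx <- cbind(round((inj$x_mm - or[1]) / sp[1]) + 1,
               round((inj$y_mm - or[2]) / sp[2]) + 1,
               round((inj$z_mm - or[3]) / sp[3]) + 1)
  expect_true(all(voxelData(gtv)[idx]))
  # coverage is non-decreasing across greedy iterations
  expect_true(all(diff(c(0, plan@iterationLog)) >= 0))
  # tour order is a permutation of the injections
  expect_setequal(plan@tourOrder, seq_len(nrow(inj)))
  # re-simulating the plan through the dose engine reproduces coverage
  dose <- computeDose(depositActivity(plan, gtv), buildDefaultKernel(),
                      Radionuclide())
  ev <- evaluatePlan(plan, gtv, dose, cfg)
  expect_equal(ev$coverage, plan@achievedCoverage, tolerance = 1e-9)
  # determinism
  plan2 <- greedyPlan(gtv, cfg)
  expect_identical(plan2@injections, plan@injections)
})

test_that("injection count grows with tumor diameter", {
  counts <- vapply(c(10, 15), function(diam) {
    gtv <- sphereMask(diam, 1, marginVox = 5)
    nrow(greedyPlan(gtv)@injections)
  }, 1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("coverage metrics summarize a dose map correctly", {
  gtv <- sphereMask(6, 1, marginVox = 2)
  geom <- voxelData(gtv)
  uniform <- VoxelVolume(array(100, dim(geom)), voxelSpacing(gtv),
                         voxelOrigin(gtv), "Gy")
  ev <- evaluatePlan(NULL, gtv, uniform)
  expect_equal(ev$v60, 100); expect_equal(ev$v100, 100)
  expect_equal(ev$d95Gy, 100); expect_equal(ev$coverage, 1)
  zero <- VoxelVolume(array(0, dim(geom)), voxelSpacing(gtv),
                      voxelOrigin(gtv), "Gy")
  ev0 <- evaluatePlan(NULL, gtv, zero)
  expect_equal(ev0$v60, 0); expect_equal(ev0$v100, 0)
  # half the GTV at 120 Gy, half at 0 -> V60 = 50 %
  n <- sum(geom)
  doses <- array(0, dim(geom))
  hot <- which(geom)[seq_len(floor(n / 2))]
  doses[hot] <- 120
  half <- VoxelVolume(doses, voxelSpacing(gtv), voxelOrigin(gtv), "Gy")
  evh <- evaluatePlan(NULL, gtv, half)
  expect_equal(evh$v60, 100 * floor(n / 2) / n)
  # mismatched lattices are refused
  expect_error(evaluatePlan(NULL, gtv, emptyGrid(9)), "geometry")
})

test_that("plans serialize to JSON and back", {
  gtv <- sphereMask(6, 1, marginVox = 3)
  plan <- greedyPlan(gtv)
  path <- tempfile(fileext = ".json")
  writePlanJSON(plan, path)
  back <- readPlanJSON(path)
  expect_equal(back@injections, plan@injections)
  expect_equal(back@achievedCoverage, plan@achievedCoverage)
  expect_equal(back@feasible, plan@feasible)
})

test_that("plan configuration enforces the clinical envelope", {
  expect_error(planConfig(allowedVolumesUl = c(4, 5)), "5, 8")
  expect_error(planConfig(doseFraction = 0), "fractions")
  expect_error(planConfig(maxInjections = 0), "maxInjections")
})
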