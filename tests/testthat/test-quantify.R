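test_that("calibration recovers an exact line and validates input", {
  cc <- fitCalibration(0:4, 40 + 12 * (0:4))
  expect_equal(cc@slope, 12)
  expect_equal(cc@intercept, 40)
  expect_equal(cc@fitResidualSd, 0, tolerance = 1e-9)
  expect_equal(cc@nPoints, 5L)
  expect_error(fitCalibration(1, 52), "2 distinct")
  expect_error(fitCalibration(c(2, 2, 2), c(60, 61, 62)), "2 distinct")
})

test_that("noisy calibration recovers the slope within its standard error", {
  conc <- seq(0, 49, length.out = 50)
  hu <- withr::with_seed(3, 40 + 12 * conc + stats::rnorm(50, 0, 5))
  cc <- fitCalibration(conc, hu)
  se <- 5 / sqrt(sum((conc - mean(conc))^2))
  expect_lt(abs(cc@slope - 12), 3 * se)
})

test_that("CT inversion is exact without noise and clips below baseline", {
  m <- sphereMask(8, 1, marginVox = 3)
  ct0 <- ctModel(noiseSd = 0)
  base <- baselineMap(m, ct0)
  # baseline-only scan -> zero concentration
  hu <- renderCT(m, NULL, ct0, seed = 1)
  cc <- fitCalibration(0:4, ct0$brainHu + ct0$hoSlopeHuPerMgMl * (0:4))
  conc <- hoConcentrationMap(hu, cc, base)
  expect_true(all(voxelData(conc) == 0))
  # HU below baseline clips to zero, never negative
  low <- VoxelVolume(voxelData(base) - 50, voxelSpacing(m), voxelOrigin(m),
                     "HU")
  expect_true(all(voxelData(hoConcentrationMap(low, cc, base)) == 0))
  expect_error(hoConcentrationMap(hu, cc, baselineMap(sphereMask(6, 1), ct0)),
               "geometry")
})

test_that("concentration-to-activity conversion follows the mass chain", {
  # 0.28 mg Ho in one 1 mm^3 voxel, fraction 0.28, 2 MBq/mg -> 2 MBq
  arr <- array(0, c(5, 5, 5)); arr[3, 3, 3] <- 0.28 / 1e-3  # mg/ml
  conc <- VoxelVolume(arr, 1, c(0, 0, 0), "mg/ml")
  s2 <- HoSuspension(specificActivityMBqPerMg = 2)
  act <- activityMapFromConcentration(conc, s2, ho166, at = 0)
  expect_equal(voxelData(act)[3, 3, 3], 2)
  expect_equal(sum(voxelData(act) != 0), 1)
  expect_error(activityMapFromConcentration(conc, s2, ho166, at = -1), "at")
  # zero map maps to zero
  zero <- VoxelVolume(array(0, c(5, 5, 5)), 1, c(0, 0, 0), "mg/ml")
  expect_true(all(voxelData(activityMapFromConcentration(zero, s2, ho166))
                  == 0))
  # inverse conversion closes the loop
  back <- concentrationFromActivity(act, s2, ho166, at = 0)
  expect_equal(voxelData(back), voxelData(conc), tolerance = 1e-12)
})

test_that("plan -> deposit -> CT -> quantify closes within 1% noise-free", {
  gtv <- sphereMask(10, 1)
  plan <- rbind(oneInjection(8, 0, 0, 0), oneInjection(5, 3, -2, 1))
  act <- depositActivity(plan, gtv)
  expect_gte(sum(voxelData(act) > 0), 8)
  conc <- concentrationFromActivity(act, hoSusp, ho166)
  ct0 <- ctModel(noiseSd = 0, saturationHu = 1e5)
  postCT <- renderCT(gtv, conc, ct0, seed = 4)
  base <- baselineMap(gtv, ct0)
  cc <- fitCalibration(0:4, ct0$brainHu + ct0$hoSlopeHuPerMgMl * (0:4))
  rec <- hoConcentrationMap(postCT, cc, base)
  injected <- totalHoMassMg(conc)
  recovered <- totalHoMassMg(rec)
  expect_lt(abs(recovered - injected) / injected, 0.01)
  # and the recovered activity total matches the plan total within 2%
  actBack <- activityMapFromConcentration(rec, hoSusp, ho166)
  expect_lt(abs(sum(voxelData(actBack)) - sum(plan$activity_mbq)) /
              sum(plan$activity_mbq), 0.02)
})

test_that("calibration phantom measurements drive a faithful fit", {
  meas <- calibrationPhantom(seq(0, 50, 10), ctModel(noiseSd = 2),
                             nVoxels = 100, seed = 5)
  cc <- fitCalibration(meas$concentration_mg_per_ml, meas$hu)
  expect_equal(cc@slope, 12, tolerance = 0.05)
  expect_equal(cc@intercept, 35, tolerance = 1)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(meas, path, row.names = FALSE)
  cc2 <- readCalibrationCSV(path)
  expect_equal(cc2@slope, cc@slope)
})
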