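test_that("a single spherical lobe rasterizes to the analytic volume", {
  m <- sphereMask(15, 1)
  expect_s4_class(m, "VoxelVolume")
  analytic <- 4 / 3 * pi * 7.5^3
  expect_lt(abs(maskVolume(m) - analytic) / analytic, 0.02)
})

test_that("mask volume error decreases as the lattice is refined", {
  analytic <- 4 / 3 * pi * 7.5^3
  errs <- vapply(c(2, 1, 0.5), function(h)
    abs(maskVolume(sphereMask(15, h, marginVox = 2)) - analytic), 1)
  expect_true(all(diff(errs) < 0))
})

test_that("disconnected or empty lobe configurations are refused", {
  apart <- phantomSpec(list(
    list(center = c(-8, 0, 0), semiAxes = c(2, 2, 2)),
    list(center = c(8, 0, 0), semiAxes = c(2, 2, 2))),
    gridShape = c(25, 25, 25))
  expect_error(makeTumorMask(apart), "connected")
  outside <- phantomSpec(list(list(center = c(100, 0, 0),
                                   semiAxes = c(2, 2, 2))),
                         gridShape = c(25, 25, 25))
  expect_error(makeTumorMask(outside), "empty")
})

test_that("phantom generation is deterministic for a fixed spec and seed", {
  s1 <- plurilobedSpec(15, nLobes = 3, seed = 42, gridShape = c(41, 41, 41))
  s2 <- plurilobedSpec(15, nLobes = 3, seed = 42, gridShape = c(41, 41, 41))
  expect_identical(voxelData(makeTumorMask(s1)), voxelData(makeTumorMask(s2)))
  s3 <- plurilobedSpec(15, nLobes = 3, seed = 43, gridShape = c(41, 41, 41))
  expect_false(identical(voxelData(makeTumorMask(s1)),
                         voxelData(makeTumorMask(s3))))
})

test_that("plurilobed phantoms are connected and within the size envelope", {
  for (seed in 1:5) {
    m <- makeTumorMask(plurilobedSpec(18, nLobes = 4, seed = seed,
                                      gridShape = c(41, 41, 41)))
    eqd <- (6 * maskVolume(m) / pi)^(1 / 3)
    expect_gt(eqd, 10); expect_lt(eqd, 30)
  }
})

test_that("exponential growth model reproduces doublings and fits", {
  g <- growthModel(1000, 3, 14)
  expect_equal(growVolume(g, 17), 2000)
  expect_equal(growVolume(g, 14), 1000)
  expect_error(growVolume(g, 13), "reference")
  # control-animal trajectory: 787 mm^3 at D14 to 2511 mm^3 at D19
  td <- fitDoublingTime(787, 14, 2511, 19)
  expect_equal(td, 5 / log2(2511 / 787))
  expect_equal(td, 2.99, tolerance = 0.005)
  expect_equal(growVolume(growthModel(787, td, 14), 19), 2511,
               tolerance = 1e-12)
})

test_that("CT forward model is exact without noise and reproducible with", {
  m <- sphereMask(8, 1, marginVox = 3)
  ct0 <- ctModel(noiseSd = 0)
  hu <- renderCT(m, NULL, ct0, seed = 1)
  expect_true(all(voxelData(hu)[voxelData(m)] == ct0$tumorHu))
  expect_true(all(voxelData(hu)[!voxelData(m)] == ct0$brainHu))
  # linear holmium term on a single voxel
  conc <- VoxelVolume(array(0, dim(voxelData(m))), voxelSpacing(m),
                      voxelOrigin(m), units = "mg/ml")
  cArr <- voxelData(conc); cArr[8, 8, 8] <- 40
  conc <- VoxelVolume(cArr, voxelSpacing(m), voxelOrigin(m), units = "mg/ml")
  hu2 <- renderCT(m, conc, ct0, seed = 1)
  base <- if (voxelData(m)[8, 8, 8]) ct0$tumorHu else ct0$brainHu
  expect_equal(voxelData(hu2)[8, 8, 8], base + ct0$hoSlopeHuPerMgMl * 40)
  # determinism and clipping
  ctn <- ctModel(noiseSd = 5)
  expect_identical(voxelData(renderCT(m, NULL, ctn, seed = 9)),
                   voxelData(renderCT(m, NULL, ctn, seed = 9)))
  expect_false(identical(voxelData(renderCT(m, NULL, ctn, seed = 9)),
                         voxelData(renderCT(m, NULL, ctn, seed = 10))))
  ctSat <- ctModel(noiseSd = 0, saturationHu = 100)
  cArr[8, 8, 8] <- 1e5
  concBig <- VoxelVolume(cArr, voxelSpacing(m), voxelOrigin(m), "mg/ml")
  expect_equal(max(voxelData(renderCT(m, concBig, ctSat, 1))), 100)
  # geometry mismatch
  other <- VoxelVolume(array(0, c(4, 4, 4)), 1, c(0, 0, 0), "mg/ml")
  expect_error(renderCT(m, other, ct0, 1), "geometry")
})
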