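test_that("deposited activity is conserved and spheres span voxels", {
  g <- emptyGrid(17, 1)
  a <- depositActivity(oneInjection(5), g)
  expect_equal(sum(voxelData(a)), uotActivity(5, hoSusp, ho166)$activityMBq,
               tolerance = 1e-9)
  # 8 ul -> sphere radius ~1.24 mm: several voxels at 0.5 mm spacing
  g2 <- emptyGrid(33, 0.5)
  a2 <- depositActivity(oneInjection(8), g2)
  expect_gt(sum(voxelData(a2) > 0), 1)
  expect_equal(sum(voxelData(a2)),
               uotActivity(8, hoSusp, ho166)$activityMBq, tolerance = 1e-9)
  # empty plan
  empty <- oneInjection(5)[0, ]
  expect_true(all(voxelData(depositActivity(empty, g)) == 0))
  # outside site names the injection index
  bad <- rbind(oneInjection(5), oneInjection(5, x = 99))
  expect_error(depositActivity(bad, g), "injection 2")
})

test_that("dose is linear in activity and zero without sources", {
  k <- shortKernel()
  g <- emptyGrid(17, 1)
  expect_true(all(voxelData(computeDose(g, k, ho166)) == 0))
  a <- depositActivity(oneInjection(8), g)
  d1 <- voxelData(computeDose(a, k, ho166))
  a2 <- VoxelVolume(2 * voxelData(a), voxelSpacing(a), voxelOrigin(a), "MBq")
  expect_identical(voxelData(computeDose(a2, k, ho166)), 2 * d1)
  a3 <- VoxelVolume(3.7 * voxelData(a), voxelSpacing(a), voxelOrigin(a), "MBq")
  expect_equal(voxelData(computeDose(a3, k, ho166)), 3.7 * d1,
               tolerance = 1e-12)
})

test_that("all emitted energy is absorbed for interior sources", {
  k <- shortKernel(3)
  g <- emptyGrid(17, 1)  # margin 8 mm > kernel range
  a <- depositActivity(oneInjection(8), g)
  d <- computeDose(a, k, ho166)
  massKg <- prod(voxelSpacing(d)) * 1e-6
  eDep <- sum(voxelData(d)) * massKg
  eEmit <- cumulatedActivity(sum(voxelData(a)), ho166) * 1e6 *
    ho166@meanEnergyMeV * ho166@mevToJoule
  expect_lt(abs(eDep - eEmit) / eEmit, 0.01)
  # a plan of several interior UoTs conserves energy too
  plan <- rbind(oneInjection(5, -3, 0, 1), oneInjection(8, 2, 2, -1))
  a2 <- depositActivity(plan, g)
  d2 <- computeDose(a2, k, ho166)
  eEmit2 <- cumulatedActivity(sum(voxelData(a2)), ho166) * 1e6 *
    ho166@meanEnergyMeV * ho166@mevToJoule
  expect_lt(abs(sum(voxelData(d2)) * massKg - eEmit2) / eEmit2, 0.01)
})

test_that("FFT dose equals the brute-force oracle on a random 16^3 map", {
  k <- shortKernel(3)
  withr::with_seed(7, {
    arr <- array(stats::runif(16^3) * (stats::runif(16^3) < 0.05),
                 c(16, 16, 16))
  })
  a <- VoxelVolume(arr, 1, c(0, 0, 0), "MBq")
  fftD <- voxelData(computeDose(a, k, ho166))
  brute <- voxelData(bruteForceDose(a, k, ho166))
  sel <- brute > 0.01 * max(brute)
  expect_lt(max(abs(fftD[sel] - brute[sel]) / brute[sel]), 1e-6)
  expect_error(bruteForceDose(emptyGrid(40), k, ho166), "32")
})

test_that("a point source produces an octahedrally symmetric dose field", {
  k <- shortKernel(3)
  g <- emptyGrid(15, 1)
  arr <- voxelData(g); arr[8, 8, 8] <- 1
  a <- VoxelVolume(arr, 1, voxelOrigin(g), "MBq")
  d <- voxelData(computeDose(a, k, ho166))
  expect_equal(d, d[15:1, , ], tolerance = 1e-12)
  expect_equal(d, aperm(d, c(2, 1, 3)), tolerance = 1e-12)
  expect_equal(d, aperm(d, c(3, 2, 1)), tolerance = 1e-12)
})

test_that("dose maps are translation-equivariant in the interior", {
  k <- shortKernel(2)
  g <- emptyGrid(17, 1)
  arr <- voxelData(g); arr[8, 8, 8] <- 2.5
  d0 <- voxelData(computeDose(VoxelVolume(arr, 1, voxelOrigin(g), "MBq"),
                              k, ho166))
  arr2 <- voxelData(g); arr2[9, 8, 8] <- 2.5
  d1 <- voxelData(computeDose(VoxelVolume(arr2, 1, voxelOrigin(g), "MBq"),
                              k, ho166))
  expect_equal(d1[4:14, , ], d0[3:13, , ], tolerance = 1e-12)
})

test_that("dose vanishes beyond the kernel range", {
  k <- shortKernel(2)
  g <- emptyGrid(17, 1)
  arr <- voxelData(g); arr[9, 9, 9] <- 1
  a <- VoxelVolume(arr, 1, voxelOrigin(g), "MBq")
  far <- which(array(TRUE, dim(arr)), arr.ind = TRUE)
  dist <- sqrt(rowSums((far - 9)^2))
  # direct summation is exactly zero out of range; the FFT path only up
  # to spectral roundoff
  db <- voxelData(bruteForceDose(a, k, ho166))
  expect_true(all(db[far[dist > 2.01, ]] == 0))
  df <- voxelData(computeDose(a, k, ho166))
  expect_true(all(df[far[dist > 2.01, ]] <= 1e-10 * max(df)))
  expect_true(all(df >= 0))
})
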