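#' Deposit planned injections onto an activity lattice
#'
#' Rasterizes an injection plan into an activity map. Post-operative CT of
#' treated animals shows the suspension localized at the injection sites,
#' so each unit of treatment (UoT) is modelled as a uniform sphere of its
#' own liquid volume (1 µl = 1 mm^3) centered at its site; its activity is
#' spread uniformly over the voxels whose centers fall inside that sphere
#' (at minimum the containing voxel). Total activity is conserved.
#'
#' @param plan an [InjectionPlan-class], or a data.frame with columns
#'   `x_mm`, `y_mm`, `z_mm`, `volume_ul`, `activity_mbq`.
#' @param geometry a [VoxelVolume-class] providing the target lattice.
#' @return activity `VoxelVolume` (units `"MBq"`, per voxel).
#' @export
depositActivity <- function(plan, geometry) {
  inj <- if (is(plan, "InjectionPlan")) plan@injections else plan
  d <- dim(voxelData(geometry))
  sp <- voxelSpacing(geometry); or <- voxelOrigin(geometry)
  act <- array(0, d)
  if (nrow(inj)) {
    ax <- lapply(1:3, function(i) or[i] + (seq_len(d[i]) - 1) * sp[i])
    for (n in seq_len(nrow(inj))) {
      site <- c(inj$x_mm[n], inj$y_mm[n], inj$z_mm[n])
      idx <- round((site - or) / sp) + 1
      if (any(idx < 1) || any(idx > d))
        stop(sprintf("injection %d lies outside the activity grid", n))
      r <- (3 * inj$volume_ul[n] / (4 * pi))^(1 / 3)
      w <- pmax(1L, ceiling(r / sp))
      lo <- pmax(1L, idx - w); hi <- pmin(d, idx + w)
      ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
      dx2 <- (ax[[1]][ii] - site[1])^2
      dy2 <- (ax[[2]][jj] - site[2])^2
      dz2 <- (ax[[3]][kk] - site[3])^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
      if (!any(inside)) {
        act[idx[1], idx[2], idx[3]] <-
          act[idx[1], idx[2], idx[3]] + inj$activity_mbq[n]
      } else {
        a <- inj$activity_mbq[n] / sum(inside)
        sub <- act[ii, jj, kk, drop = FALSE]
        sub[inside] <- sub[inside] + a
        act[ii, jj, kk] <- sub
      }
    }
  }
  VoxelVolume(act, sp, or, units = "MBq")
}

# per-voxel emitted energy in joules over all time (physical decay only)
emittedEnergyJ <- function(activityMBq, spec) {
  cumulatedActivity(activityMBq, spec) * 1e6 *
    spec@meanEnergyMeV * spec@mevToJoule
}

#' Absorbed-dose map by dose-point-kernel convolution
#'
#' Computes the 3-D absorbed dose (Gy) delivered over all time by an
#' activity map, assuming physical decay only (no biological clearance)
#' and a homogeneous soft-tissue medium. The radial kernel is resolved to
#' voxel offsets (the source voxel keeps the sub-half-voxel energy) and
#' applied by zero-padded FFT convolution, so sources near the grid edge
#' never wrap around.
#'
#' @param act activity `VoxelVolume` (MBq per voxel at injection time).
#' @param kernel a [DoseKernel-class].
#' @param spec a [RadionuclideSpec-class].
#' @param tissueDensity medium density, g/cm^3 (default 1, water-like
#'   brain).
#' @return dose `VoxelVolume` in Gy.
#' @export
computeDose <- function(act, kernel, spec, tissueDensity = 1) {
  d <- dim(voxelData(act))
  sp <- voxelSpacing(act)
  extent <- d * sp
  if (kernel@maxRangeMm > min(extent) / 2)
    warning("kernel range exceeds half the grid extent; ",
            "the grid is padded but much energy leaves the volume")
  vk <- voxelizeKernel(kernel, sp)
  pad <- vk$half
  n <- vapply(d + 2 * pad, function(x) stats::nextn(x, c(2, 3, 5)), 1)
  A <- array(0, n)
  A[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <-
    emittedEnergyJ(voxelData(act), spec)
  K <- array(0, n)
  K[cbind(vk$offsets[, 1] %% n[1] + 1, vk$offsets[, 2] %% n[2] + 1,
          vk$offsets[, 3] %% n[3] + 1)] <- vk$fraction
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) /
    prod(n)
  e <- conv[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  e[e < 0] <- 0
  massKg <- prod(sp) * 1e-6 * tissueDensity
  VoxelVolume(e / massKg, sp, voxelOrigin(act), units = "Gy")
}

#' Brute-force dose oracle
#'
#' Same physical contract as [computeDose()] via direct summation over
#' source-target voxel pairs. Quadratic cost; refused on grids larger
#' than 32^3 voxels. Intended as an independent oracle for the FFT path.
#'
#' @inheritParams computeDose
#' @return dose `VoxelVolume` in Gy.
#' @export
bruteForceDose <- function(act, kernel, spec, tissueDensity = 1) {
  d <- dim(voxelData(act))
  if (prod(d) > 32^3)
    stop("brute-force dose is restricted to grids of at most 32^3 voxels")
  sp <- voxelSpacing(act)
  vk <- voxelizeKernel(kernel, sp)
  e <- emittedEnergyJ(voxelData(act), spec)
  out <- array(0, d)
  src <- which(e != 0, arr.ind = TRUE)
  for (s in seq_len(nrow(src))) {
    tgt <- vk$offsets + matrix(src[s, ], nrow(vk$offsets), 3, byrow = TRUE)
    ok <- tgt[, 1] >= 1 & tgt[, 1] <= d[1] &
          tgt[, 2] >= 1 & tgt[, 2] <= d[2] &
          tgt[, 3] >= 1 & tgt[, 3] <= d[3]
    out[tgt[ok, , drop = FALSE]] <- out[tgt[ok, , drop = FALSE]] +
      e[src[s, 1], src[s, 2], src[s, 3]] * vk$fraction[ok]
  }
  massKg <- prod(sp) * 1e-6 * tissueDensity
  VoxelVolume(out / massKg, sp, voxelOrigin(act), units = "Gy")
}
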