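# shared fixtures, built in code at test time

# spherical GTV of the given diameter on an odd, centered grid
sphereMask <- function(diameterMm = 15, spacingMm = 1, marginVox = 5) {
  n <- 2 * ceiling(diameterMm / 2 / spacingMm + marginVox) + 1
  sp <- phantomSpec(list(list(center = c(0, 0, 0),
                              semiAxes = rep(diameterMm / 2, 3))),
                    spacingMm = spacingMm, gridShape = rep(n, 3))
  makeTumorMask(sp)
}

# short-range kernel for fast dose tests
shortKernel <- function(maxRangeMm = 3, shellWidthMm = 0.25) {
  buildDefaultKernel(maxRangeMm = maxRangeMm, shellWidthMm = shellWidthMm)
}

ho166 <- Radionuclide()
hoSusp <- HoSuspension()

# empty activity grid centered on the origin
emptyGrid <- function(n = 17, spacingMm = 1) {
  VoxelVolume(array(0, rep(n, 3)), spacingMm,
              origin = rep(-(n - 1) / 2 * spacingMm, 3), units = "MBq")
}

oneInjection <- function(volumeUl = 8, x = 0, y = 0, z = 0,
                         susp = hoSusp, spec = ho166) {
  data.frame(x_mm = x, y_mm = y, z_mm = z, volume_ul = volumeUl,
             activity_mbq = uotActivity(volumeUl, susp, spec)$activityMBq)
}
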