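#' Fit the HU-vs-concentration calibration curve
#'
#' Ordinary least-squares line relating CT signal (HU) to local holmium
#' concentration (mg Ho per ml). In practice the curve is established per
#' scanner with a standardized phantom protocol; a linear model at fixed
#' tube voltage is the standard assumption.
#'
#' @param concentrationMgPerMl calibration concentrations, mg/ml (at
#'   least two distinct values).
#' @param hu measured HU at those concentrations.
#' @return a [CalibrationCurve-class].
#' @examples
#' cc <- fitCalibration(0:4, 40 + 12 * (0:4))
#' cc@slope  # 12
#' @export
fitCalibration <- function(concentrationMgPerMl, hu) {
  if (length(concentrationMgPerMl) < 2 ||
      length(unique(concentrationMgPerMl)) < 2)
    stop("calibration needs at least 2 distinct concentrations")
  if (length(hu) != length(concentrationMgPerMl))
    stop("'hu' and 'concentrationMgPerMl' lengths differ")
  fit <- stats::lm(hu ~ concentrationMgPerMl)
  n <- length(hu)
  new("CalibrationCurve",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      fitResidualSd = if (n > 2)
        sqrt(sum(stats::residuals(fit)^2) / (n - 2)) else 0,
      nPoints = n)
}

#' Read calibration pairs from CSV
#'
#' @param path CSV with columns `concentration_mg_per_ml` and `hu`.
#' @return a [CalibrationCurve-class].
#' @export
readCalibrationCSV <- function(path) {
  x <- utils::read.csv(path)
  need <- c("concentration_mg_per_ml", "hu")
  if (!all(need %in% names(x)))
    stop("calibration CSV needs columns: ", paste(need, collapse = ", "))
  fitCalibration(x$concentration_mg_per_ml, x$hu)
}

#' Calibration phantom measurements
#'
#' Generates synthetic known-concentration insert measurements through the
#' forward CT model: for each requested concentration, the mean HU of an
#' insert of `nVoxels` voxels with Gaussian CT noise. Standing in for the
#' scanner's standardized calibration protocol in synthetic runs.
#'
#' @param concentrations insert concentrations, mg/ml.
#' @param ct a [ctModel()]; the insert baseline is the brain baseline.
#' @param nVoxels voxels averaged per insert.
#' @param seed integer seed.
#' @return data.frame with `concentration_mg_per_ml` and `hu`.
#' @export
calibrationPhantom <- function(concentrations = seq(0, 50, by = 10),
                               ct = ctModel(), nVoxels = 64, seed = 0L) {
  withSeed(seed, {
    hu <- vapply(concentrations, function(cc) {
      mean(pmin(pmax(ct$brainHu + ct$hoSlopeHuPerMgMl * cc +
                       rnorm(nVoxels, 0, ct$noiseSd),
                     ct$floorHu), ct$saturationHu))
    }, 1)
    data.frame(concentration_mg_per_ml = concentrations, hu = hu)
  })
}

#' Invert a CT volume into a holmium concentration map
#'
#' Per voxel: `C = max(0, (HU - baseline) / slope)`. The baseline map is
#' the tissue-class HU expected without holmium (in synthetic runs, the
#' pre-operative scan rendered on the identical lattice). Negative
#' excursions from noise are clipped to zero.
#'
#' @param ctVolume HU `VoxelVolume` (post-injection scan).
#' @param curve a [CalibrationCurve-class].
#' @param baseline HU `VoxelVolume` of tissue baselines, same lattice.
#' @return concentration `VoxelVolume`, mg/ml.
#' @export
hoConcentrationMap <- function(ctVolume, curve, baseline) {
  stopIfGeometryMismatch(ctVolume, baseline)
  conc <- pmax(0, (voxelData(ctVolume) - voxelData(baseline)) / curve@slope)
  VoxelVolume(array(conc, dim(voxelData(ctVolume))),
              voxelSpacing(ctVolume), voxelOrigin(ctVolume),
              units = "mg/ml")
}

#' Convert a concentration map into an activity map
#'
#' Chains holmium mass to microparticle mass via the holmium weight
#' fraction, then to activity via the specific activity and physical
#' decay: per voxel,
#' `A = (C * voxel_ml / hoWeightFraction) * specificActivity * decay(at)`.
#'
#' @param conc concentration `VoxelVolume` (mg Ho per ml).
#' @param susp a [Suspension-class].
#' @param spec a [RadionuclideSpec-class].
#' @param at hours after the specific-activity reference time, >= 0.
#' @return activity `VoxelVolume`, MBq per voxel.
#' @export
activityMapFromConcentration <- function(conc, susp, spec, at = 0) {
  if (at < 0) stop("'at' must be >= 0")
  voxMl <- voxelVolumeMm3(conc) * 1e-3
  act <- voxelData(conc) * voxMl / susp@hoWeightFraction *
    susp@specificActivityMBqPerMg * decayFactor(spec, at)
  VoxelVolume(array(act, dim(voxelData(conc))), voxelSpacing(conc),
              voxelOrigin(conc), units = "MBq")
}

#' Concentration map implied by an activity map
#'
#' Inverse of [activityMapFromConcentration()]; used to drive the forward
#' CT model from a deposited plan in synthetic round trips.
#'
#' @inheritParams activityMapFromConcentration
#' @param act activity `VoxelVolume`, MBq per voxel.
#' @return concentration `VoxelVolume`, mg Ho per ml.
#' @export
concentrationFromActivity <- function(act, susp, spec, at = 0) {
  if (at < 0) stop("'at' must be >= 0")
  voxMl <- voxelVolumeMm3(act) * 1e-3
  conc <- voxelData(act) / (susp@specificActivityMBqPerMg *
                              decayFactor(spec, at)) *
    susp@hoWeightFraction / voxMl
  VoxelVolume(array(conc, dim(voxelData(act))), voxelSpacing(act),
              voxelOrigin(act), units = "mg/ml")
}

#' Total holmium mass in a concentration map
#'
#' @param conc concentration `VoxelVolume` (mg/ml).
#' @param mask optional boolean `VoxelVolume` restricting the total.
#' @return total holmium mass, mg.
#' @export
totalHoMassMg <- function(conc, mask = NULL) {
  v <- voxelData(conc)
  if (!is.null(mask)) {
    stopIfGeometryMismatch(conc, mask)
    v <- v[voxelData(mask)]
  }
  sum(v) * voxelVolumeMm3(conc) * 1e-3
}

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: HU = %.2f + %.2f * C(mg/ml); residual sd %.2f HU (n=%d)\n",
    object@intercept, object@slope, object@fitResidualSd, object@nPoints))
})
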