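#' @import methods
NULL

#' VoxelVolume: a 3-D scalar lattice with physical geometry
#'
#' The central imaging container of the package. A `VoxelVolume` is a dense
#' 3-D numeric array plus the physical geometry needed to interpret it:
#' voxel spacing (mm per axis) and the world position (mm) of the center of
#' voxel `[1,1,1]`. The same container carries Hounsfield units, activity
#' (MBq per voxel), holmium concentration (mg/ml) or absorbed dose (Gy),
#' distinguished by the `units` slot. Voxel positions refer to voxel
#' centers in a right-handed mm coordinate system.
#'
#' @slot voxels 3-D numeric (or logical for masks) array.
#' @slot spacing numeric(3), voxel edge lengths in mm, all > 0.
#' @slot origin numeric(3), world coordinates (mm) of the center of the
#'   first voxel.
#' @slot units single string, e.g. `"HU"`, `"MBq"`, `"mg/ml"`, `"Gy"`,
#'   `"mask"`.
#' @exportClass VoxelVolume
setClass("VoxelVolume",
  representation(
    voxels  = "array",
    spacing = "numeric",
    origin  = "numeric",
    units   = "character"
  ),
  prototype(
    spacing = c(1, 1, 1),
    origin  = c(0, 0, 0),
    units   = ""
  )
)

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "'voxels' must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite values (mm)")
  if (length(object@units) != 1L)
    msg <- c(msg, "'units' must be a single string")
  if (length(msg)) msg else TRUE
})

#' RadionuclideSpec: decay and emission constants of the therapy nuclide
#'
#' Physical constants for the radionuclide: the physical half-life driving
#' all decay kinetics and the mean energy emitted per decay that the dose
#' engine deposits locally. The default parameterizes Ho-166
#' (half-life 26.8 h); the mean beta energy per decay, 0.665 MeV, is a
#' configuration constant taken from standard nuclear-data compilations
#' (ICRP-107-style tables) — gamma emissions are excluded from the default
#' energy budget because the locally deposited beta component dominates at
#' millimeter scale.
#'
#' @slot name nuclide label.
#' @slot halfLifeHours physical half-life in hours (> 0).
#' @slot meanEnergyMeV mean (beta) energy emitted per decay, MeV (> 0).
#' @slot mevToJoule conversion constant, J per MeV.
#' @exportClass RadionuclideSpec
setClass("RadionuclideSpec",
  representation(
    name          = "character",
    halfLifeHours = "numeric",
    meanEnergyMeV = "numeric",
    mevToJoule    = "numeric"
  )
)

setValidity("RadionuclideSpec", function(object) {
  msg <- character()
  if (length(object@halfLifeHours) != 1L || !is.finite(object@halfLifeHours) ||
      object@halfLifeHours <= 0)
    msg <- c(msg, "'halfLifeHours' must be a single positive number")
  if (length(object@meanEnergyMeV) != 1L || !is.finite(object@meanEnergyMeV) ||
      object@meanEnergyMeV <= 0)
    msg <- c(msg, "'meanEnergyMeV' must be a single positive number")
  if (length(object@mevToJoule) != 1L || object@mevToJoule <= 0)
    msg <- c(msg, "'mevToJoule' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Suspension: physicochemical model of the injectable microparticle suspension
#'
#' Describes the Ho microparticle suspension as injected: dry-matter
#' concentration (g/L), holmium weight fraction of the dry matter,
#' suspension density, particle size (metadata only) and the specific
#' activity (MBq per mg of microparticles) at a stated reference time.
#' Defaults follow the manufactured suspension: 550 g/L dry matter, 28 %
#' Ho by weight, density 1.38 g/ml, 470 nm mean particle size, specific
#' activity 2.5 MBq/mg (midpoint of the achievable 2-3 MBq/mg range at
#' injection time).
#'
#' @slot dryMatterGperL dry matter concentration, g/L.
#' @slot hoWeightFraction holmium weight fraction of dry matter, in (0,1).
#' @slot densityGperMl suspension density, g/ml.
#' @slot particleMeanSizeNm mean particle diameter, nm (metadata only).
#' @slot specificActivityMBqPerMg activity per mg of microparticles at the
#'   reference time, MBq/mg.
#' @exportClass Suspension
setClass("Suspension",
  representation(
    dryMatterGperL           = "numeric",
    hoWeightFraction         = "numeric",
    densityGperMl            = "numeric",
    particleMeanSizeNm       = "numeric",
    specificActivityMBqPerMg = "numeric"
  )
)

setValidity("Suspension", function(object) {
  msg <- character()
  if (object@dryMatterGperL <= 0)
    msg <- c(msg, "'dryMatterGperL' must be > 0")
  if (object@hoWeightFraction <= 0 || object@hoWeightFraction >= 1)
    msg <- c(msg, "'hoWeightFraction' must be in (0, 1)")
  if (object@densityGperMl <= 0)
    msg <- c(msg, "'densityGperMl' must be > 0")
  if (object@specificActivityMBqPerMg < 0)
    msg <- c(msg, "'specificActivityMBqPerMg' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DoseKernel: radial energy-deposition-per-decay table
#'
#' A dose point kernel discretized on concentric spherical shells: for each
#' shell between consecutive radii, the fraction of the emitted energy per
#' decay deposited in that shell. All energy is absorbed within
#' `maxRangeMm` (fractions sum to 1), consistent with a beta emitter in
#' homogeneous soft tissue.
#'
#' @slot shellEdgesMm shell boundary radii in mm, strictly increasing,
#'   starting at 0.
#' @slot shellEnergyFraction fraction of emitted energy deposited per
#'   shell; nonnegative, sums to 1 within 1e-6.
#' @slot maxRangeMm maximum deposition range, mm (last shell edge).
#' @exportClass DoseKernel
setClass("DoseKernel",
  representation(
    shellEdgesMm        = "numeric",
    shellEnergyFraction = "numeric",
    maxRangeMm          = "numeric"
  )
)

setValidity("DoseKernel", function(object) {
  msg <- character()
  e <- object@shellEdgesMm
  f <- object@shellEnergyFraction
  if (length(e) < 2L || e[1] != 0 || any(diff(e) <= 0))
    msg <- c(msg, "'shellEdgesMm' must start at 0 and be strictly increasing")
  if (length(f) != length(e) - 1L)
    msg <- c(msg, "'shellEnergyFraction' must have one entry per shell")
  if (any(f < 0))
    msg <- c(msg, "shell fractions must be nonnegative")
  if (abs(sum(f) - 1) > 1e-6)
    msg <- c(msg, "shell fractions must sum to 1 within 1e-6")
  if (length(object@maxRangeMm) != 1L ||
      abs(object@maxRangeMm - e[length(e)]) > 1e-9)
    msg <- c(msg, "'maxRangeMm' must equal the last shell edge")
  if (length(msg)) msg else TRUE
})

#' InjectionPlan: an ordered set of unit-of-treatment injections
#'
#' The planner's output: one row per unit of treatment (UoT) giving its
#' world position (mm), liquid volume (µl) and activity at injection time
#' (MBq), together with the achieved coverage (fraction of GTV voxels at or
#' above the dose threshold), a feasibility flag, and the per-iteration
#' coverage log of the greedy search.
#'
#' @slot injections data.frame with columns `x_mm`, `y_mm`, `z_mm`,
#'   `volume_ul`, `activity_mbq`.
#' @slot achievedCoverage fraction of GTV voxels at or above
#'   `doseFraction * targetDoseGy`.
#' @slot feasible logical; TRUE when the coverage constraint was met.
#' @slot iterationLog numeric vector of coverage after each greedy step.
#' @slot tourOrder integer permutation of injection rows: a
#'   nearest-neighbor needle tour over the sites (execution-order
#'   metadata; it does not constrain placement).
#' @exportClass InjectionPlan
setClass("InjectionPlan",
  representation(
    injections       = "data.frame",
    achievedCoverage = "numeric",
    feasible         = "logical",
    iterationLog     = "numeric",
    tourOrder        = "integer"
  )
)

setValidity("InjectionPlan", function(object) {
  msg <- character()
  need <- c("x_mm", "y_mm", "z_mm", "volume_ul", "activity_mbq")
  if (!all(need %in% names(object@injections)))
    msg <- c(msg, paste("'injections' must have columns:",
                        paste(need, collapse = ", ")))
  if (length(object@achievedCoverage) != 1L ||
      object@achievedCoverage < 0 || object@achievedCoverage > 1)
    msg <- c(msg, "'achievedCoverage' must be one value in [0, 1]")
  if (length(object@feasible) != 1L)
    msg <- c(msg, "'feasible' must be a single logical")
  if (length(msg)) msg else TRUE
})

#' CalibrationCurve: linear HU-vs-holmium-concentration calibration
#'
#' The CT quantification calibration: a least-squares line relating
#' Hounsfield units to local holmium concentration (mg Ho per ml), with the
#' residual standard deviation and the number of calibration points.
#'
#' @slot slope HU per (mg Ho)/ml, > 0 for a physical calibration.
#' @slot intercept HU at zero concentration.
#' @slot fitResidualSd residual standard deviation of the fit, HU.
#' @slot nPoints number of calibration points used.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(
    slope         = "numeric",
    intercept     = "numeric",
    fitResidualSd = "numeric",
    nPoints       = "integer"
  )
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (object@slope <= 0)
    msg <- c(msg, "'slope' must be > 0")
  if (object@nPoints < 2L)
    msg <- c(msg, "'nPoints' must be >= 2")
  if (length(msg)) msg else TRUE
})

#' LogRankResult: Mantel-Cox log-rank comparison of two survival curves
#'
#' @slot statistic chi-square statistic, >= 0.
#' @slot df degrees of freedom (1 for a two-group test).
#' @slot p upper-tail chi-square p-value.
#' @slot pReported the p-value truncated to two significant figures, as a
#'   string, mirroring study-report conventions.
#' @slot observed observed event counts per group.
#' @slot expected expected event counts per group under the null.
#' @slot variance hypergeometric variance sum.
#' @exportClass LogRankResult
setClass("LogRankResult",
  representation(
    statistic = "numeric",
    df        = "numeric",
    p         = "numeric",
    pReported = "character",
    observed  = "numeric",
    expected  = "numeric",
    variance  = "numeric"
  )
)

setValidity("LogRankResult", function(object) {
  msg <- character()
  if (object@statistic < 0) msg <- c(msg, "'statistic' must be >= 0")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "'p' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
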