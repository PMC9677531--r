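#' Radionuclide constants for Ho-166
#'
#' Constructor for [RadionuclideSpec-class]. Defaults describe Ho-166: a
#' physical half-life of 26.8 h and a mean beta energy per decay of
#' 0.665 MeV taken from standard nuclear-data compilations. Only the beta
#' budget is carried by default; the high-energy gammas of Ho-166 mostly
#' escape a centimeter-scale target and are excluded from the locally
#' deposited energy (set `meanEnergyMeV` yourself to include a gamma
#' fraction).
#'
#' @param name nuclide label.
#' @param halfLifeHours physical half-life, hours.
#' @param meanEnergyMeV mean locally deposited energy per decay, MeV.
#' @return A `RadionuclideSpec`.
#' @examples
#' ho166 <- Radionuclide()
#' decayFactor(ho166, 26.8)  # 0.5
#' @export
Radionuclide <- function(name = "Ho-166", halfLifeHours = 26.8,
                         meanEnergyMeV = 0.665) {
  new("RadionuclideSpec", name = name, halfLifeHours = halfLifeHours,
      meanEnergyMeV = meanEnergyMeV, mevToJoule = 1.602e-13)
}

#' Holmium microparticle suspension
#'
#' Constructor for [Suspension-class]. Defaults describe the injectable
#' suspension: 550 g/L dry matter at 28 % holmium weight content, density
#' 1.38 g/ml, 470 nm mean particle size, and a specific activity of
#' 2.5 MBq per mg of microparticles at the reference (injection) time —
#' the midpoint of the 2-3 MBq/mg range achievable by neutron activation.
#'
#' @param dryMatterGperL dry matter concentration, g/L.
#' @param hoWeightFraction holmium weight fraction of the dry matter.
#' @param densityGperMl suspension density, g/ml.
#' @param particleMeanSizeNm mean particle size, nm (metadata).
#' @param specificActivityMBqPerMg specific activity at reference time,
#'   MBq/mg.
#' @return A `Suspension`.
#' @examples
#' susp <- HoSuspension()
#' uotActivity(5, susp, Radionuclide(), at = 0)
#' @export
HoSuspension <- function(dryMatterGperL = 550, hoWeightFraction = 0.28,
                         densityGperMl = 1.38, particleMeanSizeNm = 470,
                         specificActivityMBqPerMg = 2.5) {
  new("Suspension", dryMatterGperL = dryMatterGperL,
      hoWeightFraction = hoWeightFraction, densityGperMl = densityGperMl,
      particleMeanSizeNm = particleMeanSizeNm,
      specificActivityMBqPerMg = specificActivityMBqPerMg)
}

#' Physical decay factor
#'
#' Fraction of activity remaining after `elapsedHours` of physical decay:
#' `2^(-elapsed / halfLife)`. No biological clearance is modelled — CT
#' follow-up shows the microparticles remain at the injection sites, so
#' physical decay is the only loss process.
#'
#' @param spec a [RadionuclideSpec-class].
#' @param elapsedHours nonnegative elapsed time, hours (vectorized).
#' @return fraction(s) in (0, 1].
#' @export
decayFactor <- function(spec, elapsedHours) {
  if (any(elapsedHours < 0)) stop("'elapsedHours' must be >= 0")
  2^(-elapsedHours / spec@halfLifeHours)
}

#' Cumulated activity under physical decay only
#'
#' Time-integrated activity from injection to infinity assuming physical
#' decay is the only clearance: `A0 * T_half * 3600 / ln 2`, in MBq*s
#' (i.e. 1e6 decays).
#'
#' @param a0 activity at injection, MBq (vectorized, nonnegative).
#' @param spec a [RadionuclideSpec-class].
#' @return cumulated activity in MBq*s.
#' @examples
#' cumulatedActivity(1, Radionuclide())  # ~1.3919e5 MBq*s
#' @export
cumulatedActivity <- function(a0, spec) {
  if (any(a0 < 0)) stop("'a0' must be >= 0")
  a0 * spec@halfLifeHours * 3600 / log(2)
}

#' Mass and activity of one unit of treatment
#'
#' Converts an injected suspension volume (µl) into microparticle mass and
#' activity. Mass is `volume * dryMatter` (550 g/L is 0.55 mg/µl);
#' activity is `mass * specificActivity * decayFactor(at)` where `at` is
#' the delay in hours after the specific-activity reference time.
#'
#' @param volumeUl injected volume, µl (>= 0).
#' @param susp a [Suspension-class].
#' @param spec a [RadionuclideSpec-class].
#' @param at hours elapsed since the specific-activity reference time.
#' @return list with `particleMassMg` and `activityMBq`.
#' @export
uotActivity <- function(volumeUl, susp, spec, at = 0) {
  if (any(volumeUl < 0)) stop("'volumeUl' must be >= 0")
  if (any(at < 0)) stop("'at' must be >= 0")
  massMg <- volumeUl * susp@dryMatterGperL / 1000  # g/L == mg/ml -> mg/ul / 1000
  list(particleMassMg = massMg,
       activityMBq = massMg * susp@specificActivityMBqPerMg *
         decayFactor(spec, at))
}

setMethod("show", "RadionuclideSpec", function(object) {
  cat(sprintf("RadionuclideSpec %s: T1/2 = %g h, E_mean = %g MeV/decay\n",
              object@name, object@halfLifeHours, object@meanEnergyMeV))
})

setMethod("show", "Suspension", function(object) {
  cat(sprintf(paste0("Suspension: %g g/L dry matter, %.0f%% Ho, ",
                     "%g g/ml, %g MBq/mg at reference\n"),
              object@dryMatterGperL, 100 * object@hoWeightFraction,
              object@densityGperMl, object@specificActivityMBqPerMg))
})
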