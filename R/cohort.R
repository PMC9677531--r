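#' Two-arm cohort specification
#'
#' Parameters of the synthetic survival cohort: arm sizes, the shared
#' growth model, the volume-threshold surrogate endpoint for untreated
#' animals, the follow-up horizon and the treatment day. Per-animal
#' heterogeneity enters as log-normal jitter on the reference volume and
#' the doubling time.
#'
#' Untreated animals in the study reached clinical endpoints (severe
#' neurologic signs) 6-9 days after the treatment day; clinical signs are
#' not modellable, so a tumor-volume threshold is used as the surrogate:
#' with the default 1000 mm^3 reference volume, 3-day doubling time and
#' 5000 mm^3 threshold, the deterministic endpoint falls on day 7
#' post-treatment, inside that window.
#'
#' @param nTreated,nUntreated arm sizes.
#' @param growth a [growthModel()].
#' @param euthanasiaVolumeMm3 surrogate endpoint volume, mm^3, > 0.
#' @param horizonDays follow-up horizon in days post-treatment (default
#'   66, the scheduled euthanasia of surviving treated animals).
#' @param treatmentDay day index of treatment (default 14, days after
#'   tumor implantation).
#' @param v0SdLog,tdSdLog log-normal dispersions (sdlog) of the
#'   per-animal reference volume and doubling time; must be >= 0 (zero
#'   disables jitter).
#' @return a `CohortSpec` (validated list).
#' @export
cohortSpec <- function(nTreated = 5, nUntreated = 3, growth = growthModel(),
                       euthanasiaVolumeMm3 = 5000, horizonDays = 66,
                       treatmentDay = 14, v0SdLog = 0.2, tdSdLog = 0.05) {
  if (horizonDays <= 0) stop("'horizonDays' must be > 0")
  if (euthanasiaVolumeMm3 <= 0) stop("'euthanasiaVolumeMm3' must be > 0")
  if (v0SdLog < 0 || tdSdLog < 0)
    stop("dispersions must be >= 0")
  stopifnot(inherits(growth, "GrowthModel"))
  structure(list(nTreated = nTreated, nUntreated = nUntreated,
                 growth = growth,
                 euthanasiaVolumeMm3 = euthanasiaVolumeMm3,
                 horizonDays = horizonDays, treatmentDay = treatmentDay,
                 v0SdLog = v0SdLog, tdSdLog = tdSdLog),
            class = "CohortSpec")
}

# first integer day post-treatment at which the grown volume exceeds the
# threshold; Inf when it never does within `cap` days
firstExceedDay <- function(v0, td, threshold, cap) {
  if (v0 > threshold) return(1L)
  t <- td * log2(threshold / v0)   # real crossing time
  day <- floor(t) + 1L             # smallest integer day with V > threshold
  if (day > cap) Inf else day
}

#' Simulate a two-arm survival cohort
#'
#' Generates per-animal survival records. Untreated animals progress under
#' the growth model (with per-animal log-normal jitter on `v0` and the
#' doubling time) and experience the event on the first whole day
#' post-treatment at which tumor volume exceeds the surrogate threshold.
#' Treated animals whose planned coverage meets the planning constraint
#' are censored alive at the horizon; under-covered treated animals
#' regrow from the uncovered tumor fraction and may reach the endpoint
#' before the horizon.
#'
#' @param spec a [cohortSpec()].
#' @param coverageTreated achieved coverage fraction of the treated arm's
#'   plans, in `[0, 1]`.
#' @param seed integer seed.
#' @param coverageConstraint coverage fraction regarded as curative
#'   (default 0.95, the planner's constraint).
#' @return data.frame of survival records: `animal_id`, `arm`
#'   (`"treated"`/`"untreated"`), `time_days` (days post-treatment) and
#'   `event` (1 = death/euthanasia for cause, 0 = censored at horizon).
#' @export
simulateCohort <- function(spec, coverageTreated = 1, seed = 0L,
                           coverageConstraint = 0.95) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (coverageTreated < 0 || coverageTreated > 1)
    stop("'coverageTreated' must be in [0, 1]")
  n <- spec$nTreated + spec$nUntreated
  withSeed(seed, {
    v0 <- spec$growth$v0 * exp(rnorm(n, 0, spec$v0SdLog) - spec$v0SdLog^2 / 2)
    td <- spec$growth$doublingTime *
      exp(rnorm(n, 0, spec$tdSdLog) - spec$tdSdLog^2 / 2)
    arm <- rep(c("treated", "untreated"), c(spec$nTreated, spec$nUntreated))
    time <- numeric(n); event <- integer(n)
    for (i in seq_len(n)) {
      vEff <- if (arm[i] == "treated") {
        if (coverageTreated >= coverageConstraint) 0
        else v0[i] * (1 - coverageTreated)
      } else v0[i]
      if (vEff <= 0) {
        time[i] <- spec$horizonDays; event[i] <- 0L
      } else {
        d <- firstExceedDay(vEff, td[i], spec$euthanasiaVolumeMm3,
                            spec$horizonDays)
        if (is.finite(d)) { time[i] <- d; event[i] <- 1L }
        else { time[i] <- spec$horizonDays; event[i] <- 0L }
      }
    }
    data.frame(animal_id = sprintf("pig%02d", seq_len(n)), arm = arm,
               time_days = time, event = event,
               stringsAsFactors = FALSE)
  })
}

#' Write / read a cohort survival table
#'
#' CSV with columns `animal_id`, `arm`, `time_days`, `event` (0/1).
#'
#' @param cohort data.frame as returned by [simulateCohort()].
#' @param path file path.
#' @return `readCohortCSV` returns the data.frame; `writeCohortCSV` its
#'   path, invisibly.
#' @export
writeCohortCSV <- function(cohort, path) {
  need <- c("animal_id", "arm", "time_days", "event")
  if (!all(need %in% names(cohort)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  utils::write.csv(cohort[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "arm", "time_days", "event")
  if (!all(need %in% names(x)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  if (any(x$time_days <= 0)) stop("survival times must be > 0")
  if (!all(x$event %in% c(0, 1))) stop("'event' must be 0/1")
  x
}
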