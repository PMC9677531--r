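#' Default end-to-end run configuration
#'
#' Assembles the full configuration of a demonstration run: the synthetic
#' phantom and cohort (`synthetic` section), the suspension
#' (`suspension`), the dose kernel (`kernel`), the planner (`plan`) and
#' the CT forward model (`ct`). Every section validates against its
#' module's constructor before any computation starts.
#'
#' @param seed integer master seed for all stochastic stages.
#' @return a nested `RunConfig` list.
#' @export
defaultRunConfig <- function(seed = 0L) {
  list(
    synthetic = list(
      tumorDiameterMm = 15, nLobes = 3,
      gridShape = c(48, 48, 48), spacingMm = 1, brainRadiusMm = 25,
      cohort = list(nTreated = 5, nUntreated = 3,
                    v0 = 1000, doublingTime = 3, referenceDay = 14,
                    euthanasiaVolumeMm3 = 5000, horizonDays = 66,
                    treatmentDay = 14, v0SdLog = 0.2, tdSdLog = 0.05)
    ),
    suspension = list(dryMatterGperL = 550, hoWeightFraction = 0.28,
                      densityGperMl = 1.38, particleMeanSizeNm = 470,
                      specificActivityMBqPerMg = 2.5),
    nuclide = list(name = "Ho-166", halfLifeHours = 26.8,
                   meanEnergyMeV = 0.665),
    kernel = list(shellWidthMm = 0.1),
    plan = list(targetDoseGy = 100, doseFraction = 0.95,
                volumeFraction = 0.95, allowedVolumesUl = 5:8,
                maxInjections = 50, candidatePitchMm = 2,
                minSiteSpacingMm = 2, siteMarginMm = 1,
                injectionRateUlPerMin = 50),
    ct = list(backgroundHu = -1000, brainHu = 35, tumorHu = 60,
              hoSlopeHuPerMgMl = 12, noiseSd = 5,
              saturationHu = 3071, floorHu = -1024),
    seed = as.integer(seed)
  )
}

#' Read a run configuration from JSON
#'
#' Missing sections or fields fall back to [defaultRunConfig()] values;
#' the merged configuration is validated before use.
#'
#' @param path JSON file.
#' @param seed seed overriding the file's (and default) seed, or `NULL`.
#' @return a validated `RunConfig` list.
#' @export
readRunConfig <- function(path, seed = NULL) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- mergeConfig(defaultRunConfig(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validateRunConfig(cfg)
  cfg
}

mergeConfig <- function(base, over) {
  for (k in names(over)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
      mergeConfig(base[[k]], over[[k]]) else over[[k]]
  }
  base
}

#' Validate a run configuration (fail fast)
#'
#' Instantiates every section through its module constructor so that any
#' invalid value aborts before computation starts.
#'
#' @param cfg a `RunConfig` list.
#' @return list of constructed section objects, invisibly.
#' @export
validateRunConfig <- function(cfg) {
  syn <- cfg$synthetic
  if (is.null(syn$tumorDiameterMm) || syn$tumorDiameterMm <= 0)
    stop("config error in 'synthetic': tumor diameter must be > 0")
  co <- syn$cohort
  objs <- list(
    suspension = do.call(HoSuspension, cfg$suspension),
    nuclide = do.call(Radionuclide, cfg$nuclide),
    plan = do.call(planConfig, cfg$plan),
    ct = do.call(ctModel, cfg$ct),
    cohort = cohortSpec(
      nTreated = co$nTreated, nUntreated = co$nUntreated,
      growth = growthModel(co$v0, co$doublingTime, co$referenceDay),
      euthanasiaVolumeMm3 = co$euthanasiaVolumeMm3,
      horizonDays = co$horizonDays, treatmentDay = co$treatmentDay,
      v0SdLog = co$v0SdLog, tdSdLog = co$tdSdLog)
  )
  invisible(objs)
}

# small stable polynomial hash of a JSON-serialized object (hex string);
# enough to fingerprint configs in reports without extra dependencies
configHash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full demonstration pipeline
#'
#' Executes the whole chain on synthetic data: phantom generation,
#' treatment planning, activity deposition, dose computation, synthetic
#' post-operative CT, CT-based holmium quantification, DVH coverage
#' metrics, cohort simulation and the survival comparison. All artifacts
#' (volumes, plan, DVH, cohort table, report) are written under `outDir`;
#' the returned report contains every stage's headline numbers and is
#' bit-reproducible for a fixed `(config, seed)`.
#'
#' @param config a `RunConfig` (see [defaultRunConfig()]).
#' @param outDir output directory (created if missing), or `NULL` to
#'   skip file artifacts.
#' @return the run report, invisibly a nested list.
#' @export
runDemo <- function(config = defaultRunConfig(), outDir = NULL) {
  objs <- validateRunConfig(config)
  seed <- config$seed
  syn <- config$synthetic
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(name, vol) {
    if (!is.null(outDir)) writeVolume(vol, file.path(outDir, name))
  }

  # phantom
  pspec <- plurilobedSpec(diameterMm = syn$tumorDiameterMm,
                          nLobes = syn$nLobes, seed = seed,
                          gridShape = syn$gridShape,
                          spacingMm = syn$spacingMm,
                          brainRadiusMm = syn$brainRadiusMm)
  gtv <- makeTumorMask(pspec)
  emit("gtv.nii.gz", gtv)

  # plan + dose
  kernel <- buildDefaultKernel(shellWidthMm = config$kernel$shellWidthMm)
  plan <- greedyPlan(gtv, objs$plan, objs$suspension, objs$nuclide, kernel)
  act <- depositActivity(plan, gtv)
  dose <- computeDose(act, kernel, objs$nuclide)
  emit("dose.nii.gz", dose)
  coverage <- evaluatePlan(plan, gtv, dose, objs$plan)
  dvh <- computeDVH(dose, gtv)
  if (!is.null(outDir)) {
    writePlanJSON(plan, file.path(outDir, "plan.json"))
    writeDVHCSV(dvh, file.path(outDir, "dvh.csv"))
  }

  # synthetic post-operative CT and quantification round trip
  conc <- concentrationFromActivity(act, objs$suspension, objs$nuclide)
  postCT <- renderCT(gtv, conc, objs$ct, seed = seed + 1L)
  emit("post_ct.nii.gz", postCT)
  calib <- calibrationPhantom(ct = objs$ct, seed = seed + 2L)
  curve <- fitCalibration(calib$concentration_mg_per_ml, calib$hu)
  base <- baselineMap(gtv, objs$ct)
  recovered <- hoConcentrationMap(postCT, curve, base)
  quant <- list(
    injected_ho_mass_mg = totalHoMassMg(conc),
    recovered_ho_mass_mg = totalHoMassMg(recovered, mask = dilateForQuant(conc)),
    calibration_slope = curve@slope,
    calibration_intercept = curve@intercept)

  # cohort + survival
  co <- syn$cohort
  cspec <- cohortSpec(nTreated = co$nTreated, nUntreated = co$nUntreated,
                      growth = growthModel(co$v0, co$doublingTime,
                                           co$referenceDay),
                      euthanasiaVolumeMm3 = co$euthanasiaVolumeMm3,
                      horizonDays = co$horizonDays,
                      treatmentDay = co$treatmentDay,
                      v0SdLog = co$v0SdLog, tdSdLog = co$tdSdLog)
  cohort <- simulateCohort(cspec, coverageTreated = plan@achievedCoverage,
                           seed = seed + 3L,
                           coverageConstraint = objs$plan$volumeFraction)
  if (!is.null(outDir))
    writeCohortCSV(cohort, file.path(outDir, "cohort.csv"))
  lr <- logrankTest(cohort$time_days[cohort$arm == "treated"],
                    cohort$event[cohort$arm == "treated"],
                    cohort$time_days[cohort$arm == "untreated"],
                    cohort$event[cohort$arm == "untreated"])

  report <- list(
    config_hash = configHash(config),
    version = as.character(utils::packageVersion("microbrachy")),
    seed = seed,
    phantom = list(gtv_volume_mm3 = maskVolume(gtv),
                   equivalent_diameter_mm =
                     (6 * maskVolume(gtv) / pi)^(1 / 3)),
    plan = list(n_injections = nrow(plan@injections),
                total_volume_ul = sum(plan@injections$volume_ul),
                total_activity_mbq = sum(plan@injections$activity_mbq),
                achieved_coverage = plan@achievedCoverage,
                feasible = plan@feasible),
    dosimetry = list(v60 = dvh$v60, v100 = dvh$v100, d95_gy = dvh$d95Gy,
                     coverage_at_threshold = coverage$coverage,
                     healthy_v10 = coverage$healthyV10),
    quantification = quant,
    survival = list(summary = survivalSummary(cohort),
                    logrank_treated_vs_untreated = list(
                      statistic = lr@statistic, p = lr@p,
                      p_reported = lr@pReported))
  )
  if (!is.null(outDir))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# mask of voxels carrying holmium (the quantification support); keeps the
# noisy background's clipped-positive voxels out of recovered totals
dilateForQuant <- function(conc) {
  VoxelVolume(voxelData(conc) > 0, voxelSpacing(conc), voxelOrigin(conc),
              units = "mask")
}

#' Validate a run report against the packaged structural schema
#'
#' Checks required fields and their types per the JSON description in
#' `inst/extdata/report-schema.json` (a minimal structural contract, not
#' a full JSON-Schema implementation).
#'
#' @param report a report list from [runDemo()] or a path to its JSON.
#' @return TRUE invisibly; otherwise an error naming the missing field.
#' @export
validateReport <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "microbrachy"),
                                simplifyVector = TRUE)
  checkNode <- function(node, spec, path) {
    for (field in names(spec)) {
      sub <- spec[[field]]
      if (!field %in% names(node))
        stop("report schema violation: missing '", path, field, "'")
      if (is.list(sub)) {
        checkNode(node[[field]], sub, paste0(path, field, "."))
      } else {
        ok <- switch(sub,
          number = is.numeric(unlist(node[[field]])),
          string = is.character(node[[field]]),
          logical = is.logical(node[[field]]) ||
            identical(node[[field]], TRUE) || identical(node[[field]], FALSE),
          table = TRUE,
          TRUE)
        if (!ok)
          stop("report schema violation: '", path, field,
               "' has the wrong type (expected ", sub, ")")
      }
    }
  }
  checkNode(report, schema$fields, "")
  invisible(TRUE)
}
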