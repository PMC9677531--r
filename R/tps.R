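#' Treatment-plan configuration
#'
#' Parameters of the fewest-injections planner. The clinical objective is
#' to deliver at least `doseFraction` of `targetDoseGy` (default: 95 % of
#' 100 Gy) to at least `volumeFraction` (default 95 %) of the gross tumor
#' volume, using unit-of-treatment injections of 5-8 µl. `maxInjections`
#' (default 50) sits well above the 9-20 UoTs used per tumor in practice,
#' so the coverage constraint — not the cap — governs default runs.
#'
#' @param targetDoseGy prescription dose, Gy.
#' @param doseFraction fraction of the prescription defining the coverage
#'   threshold, in (0, 1].
#' @param volumeFraction required covered fraction of the GTV, in (0, 1].
#' @param allowedVolumesUl candidate UoT volumes, µl, all within [5, 8].
#' @param maxInjections hard cap on the number of UoTs.
#' @param candidatePitchMm pitch of the candidate-site lattice, mm
#'   (snapped to whole voxels at planning time).
#' @param minSiteSpacingMm minimum pairwise distance between chosen
#'   sites, mm.
#' @param siteMarginMm inset of candidate sites from the GTV surface, mm.
#' @param injectionRateUlPerMin injection rate metadata, µl/min.
#' @return a `PlanConfig` (validated list).
#' @export
planConfig <- function(targetDoseGy = 100, doseFraction = 0.95,
                       volumeFraction = 0.95, allowedVolumesUl = 5:8,
                       maxInjections = 50, candidatePitchMm = 2,
                       minSiteSpacingMm = 2, siteMarginMm = 1,
                       injectionRateUlPerMin = 50) {
  if (doseFraction <= 0 || doseFraction > 1 ||
      volumeFraction <= 0 || volumeFraction > 1)
    stop("dose and volume fractions must be in (0, 1]")
  if (any(allowedVolumesUl < 5 | allowedVolumesUl > 8))
    stop("allowed UoT volumes must lie within [5, 8] ul")
  if (maxInjections < 1) stop("'maxInjections' must be >= 1")
  if (candidatePitchMm <= 0 || minSiteSpacingMm < 0 || siteMarginMm < 0)
    stop("pitch must be > 0 and spacing/margin >= 0")
  structure(list(targetDoseGy = targetDoseGy, doseFraction = doseFraction,
                 volumeFraction = volumeFraction,
                 allowedVolumesUl = sort(unique(allowedVolumesUl)),
                 maxInjections = as.integer(maxInjections),
                 candidatePitchMm = candidatePitchMm,
                 minSiteSpacingMm = minSiteSpacingMm,
                 siteMarginMm = siteMarginMm,
                 injectionRateUlPerMin = injectionRateUlPerMin),
            class = "PlanConfig")
}

#' Candidate injection sites
#'
#' Discretizes the search space: a regular lattice with pitch
#' `candidatePitchMm` (snapped to whole voxels and anchored at the voxel
#' center nearest the GTV centroid) intersected with the GTV eroded by
#' `siteMarginMm` — a site is kept only if every voxel center within the
#' margin of it lies inside the GTV. If the erosion empties the lattice,
#' the GTV centroid (snapped to its voxel center) is returned as the sole
#' candidate.
#'
#' @param gtv boolean `VoxelVolume`.
#' @param config a [planConfig()].
#' @return data.frame with columns `x_mm`, `y_mm`, `z_mm` and the voxel
#'   indices `i`, `j`, `k`.
#' @export
candidateSites <- function(gtv, config = planConfig()) {
  mask <- voxelData(gtv)
  if (!is.logical(mask)) mask <- mask != 0
  if (!any(mask)) stop("GTV mask is empty")
  d <- dim(mask); sp <- voxelSpacing(gtv); or <- voxelOrigin(gtv)
  idx <- which(mask, arr.ind = TRUE)
  centroidIdx <- pmin(pmax(round(colMeans(idx)), 1), d)
  pitchVox <- pmax(1, round(config$candidatePitchMm / sp))
  latAxis <- function(i) {
    lo <- centroidIdx[i] - pitchVox[i] * floor((centroidIdx[i] - 1) / pitchVox[i])
    seq(lo, d[i], by = pitchVox[i])
  }
  lat <- as.matrix(expand.grid(i = latAxis(1), j = latAxis(2),
                               k = latAxis(3), KEEP.OUT.ATTRS = FALSE))
  lat <- lat[mask[lat], , drop = FALSE]
  # margin erosion: closed ball of voxel centers around each site
  m <- config$siteMarginMm
  bh <- pmax(0, floor(m / sp))
  ball <- as.matrix(expand.grid(-bh[1]:bh[1], -bh[2]:bh[2], -bh[3]:bh[3],
                                KEEP.OUT.ATTRS = FALSE))
  bd <- sqrt(colSums(t(ball)^2 * sp^2))
  ball <- ball[bd <= m, , drop = FALSE]
  keep <- vapply(seq_len(nrow(lat)), function(n) {
    nb <- ball + matrix(lat[n, ], nrow(ball), 3, byrow = TRUE)
    if (any(nb < 1) || any(nb[, 1] > d[1] | nb[, 2] > d[2] | nb[, 3] > d[3]))
      return(FALSE)
    all(mask[nb])
  }, logical(1))
  lat <- lat[keep, , drop = FALSE]
  if (!nrow(lat))
    lat <- matrix(centroidIdx, 1, dimnames = list(NULL, c("i", "j", "k")))
  pos <- sweep(sweep(lat - 1, 2, sp, `*`), 2, or, `+`)
  data.frame(x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
             i = lat[, 1], j = lat[, 2], k = lat[, 3])
}

# dose field of a single UoT centered on a voxel, as an odd-sized array
# whose center voxel holds the source; reused by translation for every
# candidate site (sites are voxel-aligned)
uotDoseField <- function(volumeUl, susp, spec, kernel, spacing,
                         tissueDensity = 1) {
  act <- uotActivity(volumeUl, susp, spec, at = 0)
  rDep <- (3 * volumeUl / (4 * pi))^(1 / 3)
  half <- ceiling((kernel@maxRangeMm + rDep) / spacing) + 1
  dims <- 2 * half + 1
  geom <- VoxelVolume(array(0, dims), spacing,
                      origin = -half * spacing, units = "MBq")
  inj <- data.frame(x_mm = 0, y_mm = 0, z_mm = 0, volume_ul = volumeUl,
                    activity_mbq = act$activityMBq)
  dep <- depositActivity(inj, geom)
  list(field = voxelData(computeDose(dep, kernel, spec, tissueDensity)),
       half = half, activityMBq = act$activityMBq)
}

#' Greedy fewest-injections planner
#'
#' Iteratively adds the (site, volume) pair that newly covers the most
#' GTV voxels (voxels reaching `doseFraction * targetDoseGy`), until the
#' required volume fraction is covered (`feasible = TRUE`) or the
#' injection cap is reached or no candidate adds coverage
#' (`feasible = FALSE`, with the honest achieved coverage). Ties prefer
#' the larger volume, then the site nearest the GTV centroid, then the
#' lowest candidate index, making the search deterministic. Exact
#' minimality of the injection count is not claimed; the greedy
#' maximum-marginal-coverage heuristic is the package's own strategy for
#' the stated objective.
#'
#' @param gtv boolean `VoxelVolume` (equivalent diameter should be
#'   1-30 mm; larger targets trigger a warning).
#' @param config a [planConfig()].
#' @param susp a [Suspension-class].
#' @param spec a [RadionuclideSpec-class].
#' @param kernel a [DoseKernel-class].
#' @param tissueDensity g/cm^3, forwarded to the dose engine.
#' @return an [InjectionPlan-class].
#' @export
greedyPlan <- function(gtv, config = planConfig(), susp = HoSuspension(),
                       spec = Radionuclide(), kernel = buildDefaultKernel(),
                       tissueDensity = 1) {
  mask <- voxelData(gtv)
  if (!is.logical(mask)) mask <- mask != 0
  if (!any(mask)) stop("GTV mask is empty")
  sp <- voxelSpacing(gtv); d <- dim(mask)
  eqd <- (6 * sum(mask) * prod(sp) / pi)^(1 / 3)
  if (eqd > 30)
    warning(sprintf("GTV equivalent diameter %.1f mm exceeds the 30 mm ",
                    eqd), "design envelope; planning proceeds")
  cand <- candidateSites(gtv, config)
  if (!nrow(cand)) stop("candidate site set is empty")
  vols <- sort(config$allowedVolumesUl, decreasing = TRUE)
  fields <- lapply(vols, uotDoseField, susp = susp, spec = spec,
                   kernel = kernel, spacing = sp,
                   tissueDensity = tissueDensity)
  names(fields) <- as.character(vols)
  if (!all(vapply(fields, function(f) all(is.finite(f$field)), logical(1))))
    stop("non-finite dose in the single-UoT field")
  thr <- config$doseFraction * config$targetDoseGy
  idxMask <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(sweep(sweep(idxMask - 1, 2, sp, `*`), 2,
                             voxelOrigin(gtv), `+`))
  candDist <- sqrt((cand$x_mm - centroid[1])^2 +
                   (cand$y_mm - centroid[2])^2 +
                   (cand$z_mm - centroid[3])^2)
  D <- array(0, d)
  nGtv <- sum(mask)
  chosen <- integer(0); chosenVol <- numeric(0)
  log <- numeric(0)
  addField <- function(D, f, at) {
    lo <- pmax(1, at - f$half); hi <- pmin(d, at + f$half)
    flo <- f$half + 1 - (at - lo); fhi <- f$half + 1 + (hi - at)
    D[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      D[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
      f$field[flo[1]:fhi[1], flo[2]:fhi[2], flo[3]:fhi[3]]
    D
  }
  gainAt <- function(D, f, at) {
    lo <- pmax(1, at - f$half); hi <- pmin(d, at + f$half)
    flo <- f$half + 1 - (at - lo); fhi <- f$half + 1 + (hi - at)
    dSub <- D[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    mSub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    fSub <- f$field[flo[1]:fhi[1], flo[2]:fhi[2], flo[3]:fhi[3]]
    sum(mSub & dSub < thr & dSub + fSub >= thr)
  }
  repeat {
    covered <- sum(mask & D >= thr) / nGtv
    if (covered >= config$volumeFraction || length(chosen) >= config$maxInjections)
      break
    bestGain <- 0L; bestCand <- NA_integer_; bestVol <- NA_real_
    for (v in seq_along(vols)) {
      f <- fields[[v]]
      for (ci in seq_len(nrow(cand))) {
        if (ci %in% chosen) next
        if (length(chosen)) {
          dd <- sqrt((cand$x_mm[ci] - cand$x_mm[chosen])^2 +
                     (cand$y_mm[ci] - cand$y_mm[chosen])^2 +
                     (cand$z_mm[ci] - cand$z_mm[chosen])^2)
          if (any(dd < config$minSiteSpacingMm)) next
        }
        g <- gainAt(D, f, c(cand$i[ci], cand$j[ci], cand$k[ci]))
        better <- g > bestGain ||
          (g == bestGain && g > 0 && !is.na(bestCand) &&
           candDist[ci] < candDist[bestCand] - 1e-12)
        if (better) { bestGain <- g; bestCand <- ci; bestVol <- vols[v] }
      }
      if (bestGain > 0) break  # larger volumes first; fall through only if stuck
    }
    if (bestGain == 0L) break
    f <- fields[[as.character(bestVol)]]
    D <- addField(D, f, c(cand$i[bestCand], cand$j[bestCand],
                          cand$k[bestCand]))
    chosen <- c(chosen, bestCand); chosenVol <- c(chosenVol, bestVol)
    log <- c(log, sum(mask & D >= thr) / nGtv)
  }
  coverage <- sum(mask & D >= thr) / nGtv
  inj <- data.frame(x_mm = cand$x_mm[chosen], y_mm = cand$y_mm[chosen],
                    z_mm = cand$z_mm[chosen], volume_ul = chosenVol,
                    activity_mbq = vapply(chosenVol, function(v)
                      fields[[as.character(v)]]$activityMBq, 1))
  new("InjectionPlan", injections = inj, achievedCoverage = coverage,
      feasible = coverage >= config$volumeFraction,
      iterationLog = log, tourOrder = nearestNeighborTour(inj))
}

# nearest-neighbor needle tour over injection sites (execution order
# metadata; the single needle is repositioned without withdrawal)
nearestNeighborTour <- function(inj) {
  n <- nrow(inj)
  if (n <= 1) return(seq_len(n))
  pts <- as.matrix(inj[, c("x_mm", "y_mm", "z_mm")])
  left <- seq_len(n); tour <- 1L; left <- left[-1]
  while (length(left)) {
    last <- tour[length(tour)]
    dd <- sqrt(rowSums((pts[left, , drop = FALSE] -
                        matrix(pts[last, ], length(left), 3, byrow = TRUE))^2))
    nxt <- left[which.min(dd)]
    tour <- c(tour, nxt); left <- setdiff(left, nxt)
  }
  tour
}

#' Coverage report for a plan's dose map
#'
#' Computes the coverage statistics used to judge a plan: the covered
#' fraction at the planning threshold, V60 and V100 (percent of GTV
#' voxels at or above 60 and 100 Gy, the typical external-beam target and
#' the treatment's own prescription), D95 (dose exceeded by 95 % of GTV
#' voxels), and a healthy-tissue V10 context statistic (percent of
#' non-GTV voxels at or above 10 Gy).
#'
#' @param plan an [InjectionPlan-class] (used for metadata; may be
#'   `NULL`).
#' @param gtv boolean `VoxelVolume`.
#' @param dose dose `VoxelVolume` (Gy) on the same lattice.
#' @param config a [planConfig()].
#' @return list with `coverage`, `v60`, `v100`, `d95Gy`, `healthyV10`,
#'   `nInjections`, `feasible`.
#' @export
evaluatePlan <- function(plan, gtv, dose, config = planConfig()) {
  stopIfGeometryMismatch(gtv, dose)
  doses <- voxelData(dose)[voxelData(gtv)]
  if (!length(doses)) stop("GTV mask is empty")
  thr <- config$doseFraction * config$targetDoseGy
  out <- voxelData(dose)[!voxelData(gtv)]
  list(coverage = mean(doses >= thr),
       v60 = 100 * mean(doses >= 60),
       v100 = 100 * mean(doses >= config$targetDoseGy),
       d95Gy = doseExceededByFraction(doses, 0.95),
       healthyV10 = if (length(out)) 100 * mean(out >= 10) else 0,
       nInjections = if (is.null(plan)) NA_integer_
                     else nrow(plan@injections),
       feasible = if (is.null(plan)) NA else plan@feasible)
}

# largest dose d such that at least `frac` of the voxels receive >= d
doseExceededByFraction <- function(doses, frac) {
  s <- sort(doses)
  n <- length(s)
  k <- n - ceiling(frac * n) + 1
  s[max(1, min(n, k))]
}

#' Serialize / read an injection plan
#'
#' Plans serialize to JSON with the injection table, achieved coverage,
#' feasibility, the iteration log and needle-tour order.
#'
#' @param plan an `InjectionPlan`.
#' @param path output path.
#' @return `readPlanJSON` returns an `InjectionPlan`; `writePlanJSON` the
#'   path, invisibly.
#' @export
writePlanJSON <- function(plan, path) {
  jsonlite::write_json(
    list(injections = plan@injections,
         achieved_coverage = plan@achievedCoverage,
         feasible = plan@feasible,
         iteration_log = plan@iterationLog,
         tour_order = plan@tourOrder),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePlanJSON
#' @export
readPlanJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  inj <- as.data.frame(x$injections)
  if (!nrow(inj))
    inj <- data.frame(x_mm = numeric(0), y_mm = numeric(0),
                      z_mm = numeric(0), volume_ul = numeric(0),
                      activity_mbq = numeric(0))
  new("InjectionPlan", injections = inj,
      achievedCoverage = x$achieved_coverage, feasible = x$feasible,
      iterationLog = as.numeric(x$iteration_log),
      tourOrder = as.integer(x$tour_order))
}

setMethod("show", "InjectionPlan", function(object) {
  cat(sprintf("InjectionPlan: %d UoT(s), %.1f%% coverage, %s\n",
              nrow(object@injections), 100 * object@achievedCoverage,
              if (object@feasible) "feasible" else "NOT feasible"))
  if (nrow(object@injections)) {
    cat(sprintf("  volumes: %s ul; total activity %.1f MBq\n",
                paste(object@injections$volume_ul, collapse = ", "),
                sum(object@injections$activity_mbq)))
  }
})
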