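#' Run an expression with a local, restorable RNG state
#'
#' All stochastic operations in the package take an explicit integer seed
#' and leave the caller's RNG state untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification of a plurilobed tumor phantom
#'
#' Describes a tumor as a union of (rotated) ellipsoidal lobes inside a
#' spherical brain, on a regular voxel lattice. Contrast-enhanced
#' glioblastoma xenografts in this model present with clear boundaries and
#' a plurilobed shape, which a small union of overlapping ellipsoids
#' reproduces. All lobes must pairwise overlap transitively so that the
#' mask is a single connected component.
#'
#' @param lobes list of lobes; each lobe is a list with `center` (mm,
#'   length 3), `semiAxes` (mm, length 3) and optional `rotation` (Euler
#'   angles in degrees, length 3, applied z-y-x).
#' @param brainRadiusMm radius of the spherical brain region, mm.
#' @param spacingMm voxel spacing, mm (scalar or length 3).
#' @param gridShape voxel counts per axis, length 3.
#' @param originMm world position of the first voxel center; default
#'   centers the grid on the world origin.
#' @param seed integer seed recorded with the spec (used by random
#'   phantom generation; mask rasterization itself is deterministic).
#' @return a `PhantomSpec` (validated list).
#' @seealso [makeTumorMask()], [plurilobedSpec()]
#' @export
phantomSpec <- function(lobes, brainRadiusMm = 25, spacingMm = 1,
                        gridShape = c(48, 48, 48), originMm = NULL,
                        seed = 0L) {
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 3L)
  if (any(spacingMm <= 0)) stop("'spacingMm' must be > 0")
  if (length(gridShape) != 3L || any(gridShape < 1))
    stop("'gridShape' must be 3 positive voxel counts")
  if (!length(lobes)) stop("at least one lobe is required")
  for (lb in lobes) {
    if (is.null(lb$center) || length(lb$center) != 3L)
      stop("each lobe needs a length-3 'center' (mm)")
    if (is.null(lb$semiAxes) || length(lb$semiAxes) != 3L ||
        any(lb$semiAxes <= 0))
      stop("each lobe needs 3 positive 'semiAxes' (mm)")
  }
  if (is.null(originMm))
    originMm <- -(gridShape - 1) * spacingMm / 2
  structure(list(lobes = lobes, brainRadiusMm = brainRadiusMm,
                 spacingMm = spacingMm, gridShape = as.integer(gridShape),
                 originMm = originMm, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Random plurilobed phantom spec
#'
#' Draws a plurilobed tumor: a main ellipsoid of roughly the requested
#' equivalent diameter plus satellite lobes offset by less than their
#' combined semi-axes, guaranteeing overlap.
#'
#' @param diameterMm target equivalent diameter of the main lobe, mm
#'   (study tumors are 10-30 mm).
#' @param nLobes number of lobes (>= 1).
#' @param seed integer seed.
#' @param ... forwarded to [phantomSpec()] (grid geometry).
#' @return a `PhantomSpec`.
#' @export
plurilobedSpec <- function(diameterMm = 15, nLobes = 3, seed = 0L, ...) {
  withSeed(seed, {
    r <- diameterMm / 2
    main <- list(center = c(0, 0, 0),
                 semiAxes = r * runif(3, 0.85, 1.1),
                 rotation = runif(3, 0, 180))
    lobes <- list(main)
    if (nLobes > 1) {
      for (i in seq_len(nLobes - 1)) {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        sat <- r * runif(1, 0.35, 0.55)
        off <- dir * (min(main$semiAxes) * runif(1, 0.6, 0.9))
        lobes[[i + 1]] <- list(center = off,
                               semiAxes = sat * runif(3, 0.8, 1.2),
                               rotation = runif(3, 0, 180))
      }
    }
    phantomSpec(lobes, seed = seed, ...)
  })
}

# z-y-x Euler rotation matrix, angles in degrees
eulerRotation <- function(angles) {
  a <- angles * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  rz %*% ry %*% rx
}

# logical array marking voxel centers inside one rotated ellipsoid
rasterizeLobe <- function(lobe, centers, gridShape) {
  rot <- eulerRotation(if (is.null(lobe$rotation)) c(0, 0, 0) else lobe$rotation)
  q <- (centers - matrix(lobe$center, nrow(centers), 3, byrow = TRUE)) %*% rot
  inside <- (q[, 1] / lobe$semiAxes[1])^2 + (q[, 2] / lobe$semiAxes[2])^2 +
    (q[, 3] / lobe$semiAxes[3])^2 <= 1
  array(inside, gridShape)
}

#' Rasterize a tumor mask from a phantom spec
#'
#' Marks every voxel whose center lies inside at least one lobe. The lobe
#' set must form one connected component (checked on the voxel lattice via
#' pairwise lobe intersections); a disconnected or empty configuration is
#' an error. The reported mask volume is voxel count times voxel volume.
#'
#' @param spec a `PhantomSpec` from [phantomSpec()].
#' @return a boolean [VoxelVolume-class] with units `"mask"`.
#' @examples
#' sp <- phantomSpec(list(list(center = c(0, 0, 0), semiAxes = c(7.5, 7.5, 7.5))),
#'                   gridShape = c(24, 24, 24))
#' m <- makeTumorMask(sp)
#' maskVolume(m)  # close to the 1767 mm^3 analytic sphere volume
#' @export
makeTumorMask <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  vol <- VoxelVolume(array(FALSE, spec$gridShape), spec$spacingMm,
                     spec$originMm, units = "mask")
  centers <- voxelCenters(vol)
  lobeMasks <- lapply(spec$lobes, rasterizeLobe, centers = centers,
                      gridShape = spec$gridShape)
  mask <- Reduce(`|`, lobeMasks)
  if (!any(mask))
    stop("phantom configuration error: tumor mask is empty on this grid")
  nl <- length(lobeMasks)
  if (nl > 1) {
    # union-find over the lobe intersection graph
    parent <- seq_len(nl)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nl - 1)) for (j in (i + 1):nl)
      if (any(lobeMasks[[i]] & lobeMasks[[j]])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    if (length(unique(vapply(seq_len(nl), find, 1L))) > 1L)
      stop("phantom configuration error: lobes do not form one connected tumor")
  }
  eqd <- (6 * sum(mask) * prod(spec$spacingMm) / pi)^(1 / 3)
  if (eqd < 1 || eqd > 30)
    stop(sprintf(paste0("phantom configuration error: equivalent diameter ",
                        "%.1f mm outside the supported 1-30 mm range"), eqd))
  VoxelVolume(mask, spec$spacingMm, spec$originMm, units = "mask")
}

#' Spherical brain mask matching a phantom spec
#'
#' @param spec a `PhantomSpec`.
#' @param centerMm center of the brain sphere (default world origin).
#' @return boolean `VoxelVolume`.
#' @export
brainMask <- function(spec, centerMm = c(0, 0, 0)) {
  vol <- VoxelVolume(array(FALSE, spec$gridShape), spec$spacingMm,
                     spec$originMm, units = "mask")
  centers <- voxelCenters(vol)
  d2 <- rowSums((centers - matrix(centerMm, nrow(centers), 3, byrow = TRUE))^2)
  VoxelVolume(array(d2 <= spec$brainRadiusMm^2, spec$gridShape),
              spec$spacingMm, spec$originMm, units = "mask")
}

#' Exponential tumor growth model
#'
#' `V(day) = v0 * 2^((day - referenceDay) / doublingTime)`. Serial CT
#' volumetry of the untreated xenografts between implantation and
#' euthanasia is consistent with exponential growth with a doubling time
#' of roughly 2.3-5.8 days; the default is 3 days.
#'
#' @param v0 volume (mm^3) at the reference day, > 0.
#' @param doublingTime doubling time, days, > 0.
#' @param referenceDay day index at which `v0` is measured (default 14,
#'   the treatment day).
#' @return a `GrowthModel` (validated list).
#' @export
growthModel <- function(v0 = 1000, doublingTime = 3, referenceDay = 14) {
  if (v0 <= 0) stop("'v0' must be > 0")
  if (doublingTime <= 0) stop("'doublingTime' must be > 0")
  structure(list(v0 = v0, doublingTime = doublingTime,
                 referenceDay = referenceDay), class = "GrowthModel")
}

#' Evaluate the growth model at a given day
#'
#' @param model a `GrowthModel`.
#' @param day day index, >= the model's reference day (vectorized).
#' @return volume(s) in mm^3.
#' @examples
#' growVolume(growthModel(1000, 3, 14), 17)  # one doubling: 2000
#' @export
growVolume <- function(model, day) {
  stopifnot(inherits(model, "GrowthModel"))
  if (any(day < model$referenceDay))
    stop("'day' must not precede the model reference day")
  model$v0 * 2^((day - model$referenceDay) / model$doublingTime)
}

#' Fit a doubling time from two volume measurements
#'
#' Solves `v1 = v0 * 2^((day1 - day0)/Td)` for `Td`.
#'
#' @param v0,day0 earlier volume (mm^3) and its day.
#' @param v1,day1 later volume (mm^3) and its day; requires `v1 > v0` and
#'   `day1 > day0`.
#' @return doubling time in days.
#' @examples
#' fitDoublingTime(787, 14, 2511, 19)  # ~2.99 d
#' @export
fitDoublingTime <- function(v0, day0, v1, day1) {
  if (v0 <= 0 || v1 <= v0) stop("need 0 < v0 < v1 for a growth fit")
  if (day1 <= day0) stop("need day1 > day0")
  (day1 - day0) / log2(v1 / v0)
}

#' CT forward model parameters
#'
#' Piecewise-constant tissue baselines plus a linear holmium signal term
#' and additive Gaussian noise, clipped to a 12-bit CT range. The tumor
#' baseline exceeds the brain baseline, mimicking contrast enhancement.
#'
#' @param backgroundHu,brainHu,tumorHu class baselines, HU.
#' @param hoSlopeHuPerMgMl HU increase per (mg Ho)/ml of local
#'   concentration, > 0.
#' @param noiseSd additive Gaussian noise standard deviation, HU, >= 0.
#' @param saturationHu,floorHu clip limits (12-bit CT range).
#' @return a `CTModel` (validated list).
#' @export
ctModel <- function(backgroundHu = -1000, brainHu = 35, tumorHu = 60,
                    hoSlopeHuPerMgMl = 12, noiseSd = 5,
                    saturationHu = 3071, floorHu = -1024) {
  if (hoSlopeHuPerMgMl <= 0) stop("'hoSlopeHuPerMgMl' must be > 0")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  if (tumorHu <= brainHu) stop("tumor baseline must exceed brain baseline")
  structure(list(backgroundHu = backgroundHu, brainHu = brainHu,
                 tumorHu = tumorHu, hoSlopeHuPerMgMl = hoSlopeHuPerMgMl,
                 noiseSd = noiseSd, saturationHu = saturationHu,
                 floorHu = floorHu), class = "CTModel")
}

#' Tissue baseline HU map for a phantom
#'
#' @param tumorMask boolean `VoxelVolume`.
#' @param ct a `CTModel`.
#' @param brain optional boolean `VoxelVolume` delimiting brain tissue;
#'   when absent everything outside the tumor is treated as brain
#'   (homogeneous head phantom).
#' @return HU `VoxelVolume` of class baselines (no holmium, no noise).
#' @export
baselineMap <- function(tumorMask, ct, brain = NULL) {
  base <- array(ct$brainHu, dim(voxelData(tumorMask)))
  if (!is.null(brain)) {
    stopIfGeometryMismatch(tumorMask, brain)
    base[!voxelData(brain)] <- ct$backgroundHu
  }
  base[voxelData(tumorMask)] <- ct$tumorHu
  VoxelVolume(base, voxelSpacing(tumorMask), voxelOrigin(tumorMask),
              units = "HU")
}

#' Render a synthetic CT volume
#'
#' Forward CT model: class baseline + linear holmium term + Gaussian
#' noise, clipped to the scanner range. Deterministic for a fixed seed.
#'
#' @param tumorMask boolean `VoxelVolume` of the tumor.
#' @param hoConcentration optional `VoxelVolume` of holmium concentration
#'   (mg/ml) on the same lattice; `NULL` for a pre-injection scan.
#' @param ct a [ctModel()].
#' @param seed integer seed for the noise field.
#' @param brain optional brain mask (see [baselineMap()]).
#' @return HU `VoxelVolume`.
#' @export
renderCT <- function(tumorMask, hoConcentration = NULL, ct = ctModel(),
                     seed = 0L, brain = NULL) {
  base <- voxelData(baselineMap(tumorMask, ct, brain))
  if (!is.null(hoConcentration)) {
    stopIfGeometryMismatch(tumorMask, hoConcentration)
    base <- base + ct$hoSlopeHuPerMgMl * voxelData(hoConcentration)
  }
  if (ct$noiseSd > 0)
    base <- base + withSeed(seed, array(rnorm(length(base), 0, ct$noiseSd),
                                        dim(base)))
  hu <- pmin(pmax(base, ct$floorHu), ct$saturationHu)
  VoxelVolume(array(hu, dim(voxelData(tumorMask))), voxelSpacing(tumorMask),
              voxelOrigin(tumorMask), units = "HU")
}
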