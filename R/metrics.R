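#' Physical volume of a binary mask
#'
#' Voxel count times per-voxel volume, the standard volumetric estimator
#' for a manual CT segmentation.
#'
#' @param mask boolean `VoxelVolume`, or a logical/0-1 array.
#' @param spacing voxel spacing in mm (taken from the `VoxelVolume` when
#'   omitted).
#' @return volume in mm^3.
#' @export
maskVolume <- function(mask, spacing = NULL) {
  if (is(mask, "VoxelVolume")) {
    spacing <- voxelSpacing(mask)
    mask <- voxelData(mask)
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!is.logical(mask) && !all(mask %in% c(0, 1)))
    stop("'mask' must be binary")
  sum(mask != 0) * prod(spacing)
}

#' Tumor volume growth ratio
#'
#' Ratio of a later to a reference volume. Untreated tumors in this model
#' reach roughly 12 times their treatment-day volume by euthanasia.
#'
#' @param vLater later volume, mm^3.
#' @param vRef reference volume, mm^3, > 0.
#' @return dimensionless ratio.
#' @examples
#' volumeRatio(11124, 871)  # ~12.8
#' @export
volumeRatio <- function(vLater, vRef) {
  if (any(vRef <= 0)) stop("reference volume must be > 0")
  vLater / vRef
}

#' Cumulative dose-volume histogram over a target mask
#'
#' Cumulative DVH of the GTV voxel doses, plus the summary coverages read
#' off the exact voxel dose multiset (not the binned curve): V60 and V100
#' (percent of GTV at or above 60 / 100 Gy) and D95 (dose exceeded by
#' 95 % of GTV voxels). 60 Gy is the typical external-beam prescription
#' for this indication; 100 Gy is the treatment's own target.
#'
#' @param dose dose `VoxelVolume`, Gy.
#' @param gtv boolean `VoxelVolume`, same lattice, non-empty.
#' @param binWidthGy histogram bin width, Gy, > 0.
#' @return a `DVHResult`: list with `doseEdgesGy`,
#'   `cumulativeVolumeFraction`, `v60`, `v100`, `d95Gy`.
#' @export
computeDVH <- function(dose, gtv, binWidthGy = 1) {
  stopIfGeometryMismatch(dose, gtv)
  if (binWidthGy <= 0) stop("'binWidthGy' must be > 0")
  doses <- voxelData(dose)[voxelData(gtv)]
  if (!length(doses)) stop("GTV mask is empty")
  edges <- seq(0, max(doses) + binWidthGy, by = binWidthGy)
  cumfrac <- vapply(edges, function(e) mean(doses >= e), 1)
  structure(list(doseEdgesGy = edges,
                 cumulativeVolumeFraction = cumfrac,
                 v60 = 100 * mean(doses >= 60),
                 v100 = 100 * mean(doses >= 100),
                 d95Gy = doseExceededByFraction(doses, 0.95)),
            class = "DVHResult")
}

#' @export
print.DVHResult <- function(x, ...) {
  cat(sprintf("DVH: V60 = %.1f%%, V100 = %.1f%%, D95 = %.1f Gy (%d bins)\n",
              x$v60, x$v100, x$d95Gy, length(x$doseEdgesGy)))
  invisible(x)
}

#' Export a DVH as a two-column CSV
#'
#' @param dvh a `DVHResult`.
#' @param path output path (columns `dose_gy`, `volume_fraction`).
#' @return the path, invisibly.
#' @export
writeDVHCSV <- function(dvh, path) {
  utils::write.csv(data.frame(dose_gy = dvh$doseEdgesGy,
                              volume_fraction = dvh$cumulativeVolumeFraction),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
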