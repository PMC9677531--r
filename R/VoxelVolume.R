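#' Construct a VoxelVolume
#'
#' @param voxels 3-D numeric or logical array.
#' @param spacing voxel spacing in mm, length 3 (recycled from length 1).
#' @param origin world coordinates (mm) of the center of voxel `[1,1,1]`.
#' @param units unit label carried with the values (`"HU"`, `"MBq"`,
#'   `"mg/ml"`, `"Gy"`, `"mask"`, ...).
#' @return A [VoxelVolume-class] object.
#' @examples
#' v <- VoxelVolume(array(0, c(4, 4, 4)), spacing = 1, units = "Gy")
#' voxelSpacing(v)
#' @export
VoxelVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        units = "") {
  if (is.logical(voxels)) storage.mode(voxels) <- "logical"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VoxelVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), units = units)
}

#' @rdname VoxelVolume
#' @param x,object a `VoxelVolume`.
#' @export
voxelData <- function(x) x@voxels

#' @rdname VoxelVolume
#' @export
voxelSpacing <- function(x) x@spacing

#' @rdname VoxelVolume
#' @export
voxelOrigin <- function(x) x@origin

#' @rdname VoxelVolume
#' @export
voxelUnits <- function(x) x@units

#' @rdname VoxelVolume
#' @details `voxelVolumeMm3()` returns the physical volume of one voxel in
#'   mm^3.
#' @export
voxelVolumeMm3 <- function(x) prod(voxelSpacing(x))

#' World coordinates of voxel centers
#'
#' Returns the world coordinate (mm) of each lattice position along one
#' axis, or the full n-by-3 matrix of voxel-center coordinates.
#'
#' @param x a `VoxelVolume`.
#' @param axis axis index 1..3, or `NULL` for the full coordinate matrix
#'   (one row per voxel, in array order).
#' @return numeric vector or matrix of mm coordinates.
#' @export
voxelCenters <- function(x, axis = NULL) {
  d <- dim(voxelData(x))
  ax <- function(i) voxelOrigin(x)[i] + (seq_len(d[i]) - 1) * voxelSpacing(x)[i]
  if (!is.null(axis)) return(ax(axis))
  g <- expand.grid(ax(1), ax(2), ax(3), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("x_mm", "y_mm", "z_mm"))
  m
}

#' Check that two volumes share lattice geometry
#'
#' @param a,b `VoxelVolume` objects.
#' @param tol tolerance in mm on spacing and origin.
#' @return TRUE invisibly; otherwise an error.
#' @export
stopIfGeometryMismatch <- function(a, b, tol = 1e-6) {
  if (!identical(dim(voxelData(a)), dim(voxelData(b))) ||
      any(abs(voxelSpacing(a) - voxelSpacing(b)) > tol) ||
      any(abs(voxelOrigin(a) - voxelOrigin(b)) > tol))
    stop("voxel volumes do not share lattice geometry ",
         "(dimensions, spacing and origin must match)")
  invisible(TRUE)
}

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VoxelVolume %dx%dx%d [%s]\n", d[1], d[2], d[3],
              if (nzchar(object@units)) object@units else "unitless"))
  cat(sprintf("  spacing: %s mm; origin: %s mm\n",
              paste(format(object@spacing), collapse = " x "),
              paste(format(object@origin), collapse = ", ")))
  v <- object@voxels
  if (is.logical(v)) {
    cat(sprintf("  mask: %d of %d voxels set\n", sum(v), length(v)))
  } else {
    cat(sprintf("  range: [%g, %g]; sum: %g\n", min(v), max(v), sum(v)))
  }
})
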