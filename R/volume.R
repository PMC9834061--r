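#' Density volume container
#'
#' A `tomo_volume` is the universal currency of the package: a 3D scalar grid
#' together with its physical voxel size in Angstrom and the physical
#' coordinate of voxel (1,1,1). All coordinates in metadata tables are
#' physical Angstrom, never voxels, so that tables survive rebinning.
#'
#' @param data numeric 3D array (dimensions `nx, ny, nz`).
#' @param voxel_size isotropic voxel edge length in Angstrom (> 0).
#' @param origin numeric length-3, physical coordinate (Angstrom) of the
#'   center of the first voxel. Defaults to `c(0, 0, 0)`.
#' @return An object of class `tomo_volume`.
#' @export
new_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (Angstrom)")
  if (!all(is.finite(data))) stop("volume data must be finite")
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "tomo_volume"
  )
}

is_volume <- function(x) inherits(x, "tomo_volume")

stopifnot_volume <- function(x) {
  if (!is_volume(x)) stop("expected a `tomo_volume` object")
  invisible(x)
}

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tomo_volume> %d x %d x %d voxels @ %.3f A/voxel (%.1f x %.1f x %.1f A)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  origin (A): %.2f %.2f %.2f  range: [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.tomo_volume <- function(x) dim(x$data)

# Physical center of the grid in Angstrom (voxel-center convention).
vol_center <- function(vol) {
  vol$origin + (dim(vol$data) - 1) / 2 * vol$voxel_size
}

# Zero-based voxel coordinate of a physical point.
phys_to_voxel <- function(vol, xyz) {
  (xyz - vol$origin) / vol$voxel_size
}

voxel_to_phys <- function(vol, ijk0) {
  vol$origin + ijk0 * vol$voxel_size
}

# Replace the data grid, keeping metadata.
with_data <- function(vol, data) {
  vol$data <- data
  vol
}

#' Normalized cross-correlation of two volumes
#'
#' Pearson correlation of voxel values, optionally restricted to a mask.
#' Used throughout as the scale-invariant similarity score between maps.
#'
#' @param a,b `tomo_volume` objects or arrays on identical grids.
#' @param mask optional logical array selecting the voxels to compare.
#' @return correlation in \[-1, 1\].
#' @export
vol_correlation <- function(a, b, mask = NULL) {
  xa <- if (is_volume(a)) a$data else a
  xb <- if (is_volume(b)) b$data else b
  if (!identical(dim(xa), dim(xb))) stop("volumes must share a grid")
  if (!is.null(mask)) {
    xa <- xa[mask]
    xb <- xb[mask]
  }
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) return(0)
  stats::cor(as.vector(xa), as.vector(xb))
}
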