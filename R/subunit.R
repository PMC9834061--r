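#' Pseudo-atomic subunit density models
#'
#' Builds a small centered density used as the building block of synthetic
#' filaments and particle fields. Three shapes are available:
#' `gaussian_blob` (isotropic Gaussian whose full width at half maximum
#' equals `diameter`), `two_lobe` (two unequal Gaussian lobes along the
#' intrinsic z axis — an asymmetric, polar subunit, loosely mimicking the
#' two-domain shape of an actin monomer), and `sphere_shell` (density
#' maximal on a shell of the given diameter, near zero at the center).
#' The maximum density is 1 and the support is compact within the box.
#'
#' @param kind one of `"gaussian_blob"`, `"two_lobe"`, `"sphere_shell"`.
#' @param diameter characteristic size in Angstrom (FWHM for the Gaussian
#'   shapes, shell diameter for `sphere_shell`).
#' @param voxel_size voxel size in Angstrom.
#' @param box box size in voxels (odd recommended); defaults to the
#'   smallest odd box with ~30% margin around the subunit.
#' @return a `tomo_volume` with max density 1.
#' @export
make_subunit_model <- function(kind = c("gaussian_blob", "two_lobe",
                                        "sphere_shell"),
                               diameter, voxel_size, box = NULL) {
  kind <- match.arg(kind)
  if (diameter <= 0) stop("diameter must be positive")
  if (is.null(box)) {
    box <- ceiling(1.6 * diameter / voxel_size)
    if (box %% 2 == 0) box <- box + 1
  }
  if (diameter >= box * voxel_size)
    stop(sprintf("diameter (%.1f A) must be smaller than the box edge (%.1f A)",
                 diameter, box * voxel_size))
  cc <- (box - 1) / 2
  ax <- ((0:(box - 1)) - cc) * voxel_size
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  r <- sqrt(r2)
  half_box <- (box - 1) / 2 * voxel_size

  data <- switch(kind,
    gaussian_blob = {
      sigma <- diameter / (2 * sqrt(2 * log(2)))
      exp(-r2 / (2 * sigma^2))
    },
    two_lobe = {
      z <- array(rep(ax, each = box * box), dim = rep(box, 3))
      rho2 <- r2 - z^2                       # squared distance from the z axis
      s1 <- 0.19 * diameter                  # larger lobe
      s2 <- 0.15 * diameter                  # smaller lobe
      off <- 0.25 * diameter
      exp(-(rho2 + (z - off)^2) / (2 * s1^2)) +
        0.75 * exp(-(rho2 + (z + off)^2) / (2 * s2^2))
    },
    sphere_shell = {
      sigma <- max(voxel_size, diameter / 10)
      exp(-(r - diameter / 2)^2 / (2 * sigma^2))
    })

  # enforce compact support inside the box
  data[r > half_box] <- 0
  data <- data / max(data)
  new_volume(data, voxel_size)
}

#' Soft-edged solid sphere density
#'
#' Density 1 inside `radius`, falling to 0 over a cosine edge. Used as a
#' well-defined "extra density" (e.g. an rRNA expansion-segment mimic)
#' whose half-maximum volume is (4/3) pi radius^3.
#'
#' @param radius sphere radius in Angstrom.
#' @param voxel_size voxel size in Angstrom.
#' @param edge cosine edge width in Angstrom (default one voxel each way).
#' @param box optional box size in voxels.
#' @return a `tomo_volume` with max density 1.
#' @export
make_solid_sphere <- function(radius, voxel_size, edge = 2 * voxel_size,
                              box = NULL) {
  if (is.null(box)) {
    box <- ceiling(2 * (radius + 2 * edge) / voxel_size)
    if (box %% 2 == 0) box <- box + 1
  }
  cc <- (box - 1) / 2
  ax <- ((0:(box - 1)) - cc) * voxel_size
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  m <- 0.5 * (1 + cos(pi * (r - (radius - edge / 2)) / edge))
  m[r <= radius - edge / 2] <- 1
  m[r >= radius + edge / 2] <- 0
  new_volume(m, voxel_size)
}
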