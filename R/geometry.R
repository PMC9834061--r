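#' Rotations and volume resampling
#'
#' The package-wide angle convention is intrinsic ZYZ Euler angles in
#' degrees, describing the rotation that takes the reference frame into the
#' particle: `R = Rz(phi) %*% Ry(theta) %*% Rz(psi)`. Axes form a
#' right-handed system; the beam direction of the simulated tilt geometry
#' is +z.
#'
#' @name geometry
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Euler angles (intrinsic ZYZ, degrees) to rotation matrix
#' @param phi,theta,psi Euler angles in degrees.
#' @return 3x3 rotation matrix `Rz(phi) Ry(theta) Rz(psi)`.
#' @export
euler_to_matrix <- function(phi, theta, psi) {
  rot_z(phi) %*% rot_y(theta) %*% rot_z(psi)
}

#' Rotation matrix to intrinsic ZYZ Euler angles (degrees)
#' @param R a 3x3 rotation matrix.
#' @return numeric `c(phi, theta, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  theta <- acos(max(-1, min(1, R[3, 3])))
  if (abs(sin(theta)) > 1e-8) {
    phi <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  } else {
    phi <- atan2(R[2, 1], R[1, 1])
    psi <- 0
    if (R[3, 3] < 0) phi <- -atan2(R[2, 1], R[1, 1])
  }
  rad2deg(c(phi = phi, theta = theta, psi = psi))
}

# Rotation taking unit vector u onto unit vector v (Rodrigues formula).
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(w^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any axis orthogonal to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- a - sum(a * u) * u
    w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Rigidly transform a volume about its center
#'
#' Applies the object transform "rotate by `R`, then translate by
#' `shift` (Angstrom)" with trilinear resampling; samples falling outside
#' the input grid become 0.
#'
#' @param vol a `tomo_volume`.
#' @param R 3x3 rotation matrix.
#' @param shift length-3 translation in Angstrom.
#' @return transformed `tomo_volume` on the same grid.
#' @export
rotate_volume <- function(vol, R = diag(3), shift = c(0, 0, 0)) {
  stopifnot_volume(vol)
  d <- dim(vol$data)
  cv <- (d - 1) / 2
  tv <- shift / vol$voxel_size
  A <- t(R)
  b <- cv - A %*% (cv + tv)
  out <- cpp_resample3d(vol$data, A, as.numeric(b), as.integer(d))
  with_data(vol, out)
}

# Resample a cubic oriented region out of a source volume in one
# interpolation pass. The output grid is `box^3` at the source voxel size,
# centered on `center` (Angstrom, source frame); the object appears rotated
# by R (e.g. R maps a filament tangent onto +z).
resample_oriented <- function(vol, center, R, box) {
  d <- dim(vol$data)
  p <- phys_to_voxel(vol, center)
  co <- (box - 1) / 2
  A <- t(R)
  b <- p - A %*% rep(co, 3)
  out <- cpp_resample3d(vol$data, A, as.numeric(b), as.integer(rep(box, 3)))
  new_volume(out, vol$voxel_size,
             origin = center - co * vol$voxel_size)
}
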