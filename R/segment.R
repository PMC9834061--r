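#' Segment a filament trace at fixed arc-length spacing
#'
#' Places segments at arc positions 0, s, 2s, ... along the interpolated
#' centerline (count = floor(L / s) + 1). Each segment carries its center
#' (Angstrom), the unit tangent of the curve, and initial ZYZ Euler angles
#' describing the minimal rotation taking the +z axis onto the tangent
#' (in-plane azimuth is left at 0; it is a search parameter downstream).
#' The default spacing of 32.13 Angstrom matches the study's intersegment
#' distance.
#'
#' @param trace a [filament_trace()].
#' @param spacing intersegment distance in Angstrom (> 0).
#' @return a segment table (particle table with `tangent_x/y/z`,
#'   `filament_id` and `arc_position` columns).
#' @export
segment_trace <- function(trace, spacing = 32.13) {
  stopifnot(inherits(trace, "filament_trace"))
  if (spacing <= 0) stop("spacing must be positive")
  fr <- trace_frames(trace)
  if (fr$length < spacing) {
    warning(sprintf("trace length (%.1f A) below spacing (%.2f A): single segment at arc 0",
                    fr$length, spacing))
    s <- 0
  } else {
    s <- seq(0, floor(fr$length / spacing) * spacing, by = spacing)
  }
  f <- frames_at(fr, s)
  eul <- t(vapply(seq_along(s), function(i) {
    matrix_to_euler(rotation_between(c(0, 0, 1), f$T[i, ]))
  }, numeric(3)))
  df <- data.frame(
    particle_id = paste0("f", trace$filament_id, "_s", seq_along(s)),
    source_volume_id = trace$source_volume_id,
    filament_id = trace$filament_id,
    arc_position = s,
    center_x = f$P[, 1], center_y = f$P[, 2], center_z = f$P[, 3],
    euler_phi = eul[, 1], euler_theta = eul[, 2], euler_psi = eul[, 3],
    tangent_x = f$T[, 1], tangent_y = f$T[, 2], tangent_z = f$T[, 3],
    stringsAsFactors = FALSE)
  validate_particle_table(df)
  df
}

#' Extract cubic subvolumes at segment centers
#'
#' Cuts one `box`^3 subvolume per segment, centered on the segment center
#' with trilinear interpolation for sub-voxel centers. Segments whose box
#' does not fit fully inside the volume are dropped and the count logged.
#'
#' @param volume the source `tomo_volume`.
#' @param table a segment/particle table with `center_x/y/z` in Angstrom.
#' @param box box size in voxels (even).
#' @return list of `tomo_volume`s; attribute `"kept"` holds the retained
#'   row indices, attribute `"n_dropped"` the number dropped.
#' @export
extract_subvolumes <- function(volume, table, box) {
  stopifnot_volume(volume)
  if (box %% 2 != 0) stop("box must be even")
  d <- dim(volume$data)
  if (any(box > d)) stop("box larger than the source volume")
  half <- (box - 1) / 2
  out <- list()
  kept <- integer(0)
  for (i in seq_len(nrow(table))) {
    ctr <- c(table$center_x[i], table$center_y[i], table$center_z[i])
    p <- phys_to_voxel(volume, ctr)
    if (any(p - half < -1e-9) || any(p + half > d - 1 + 1e-9)) next
    kept <- c(kept, i)
    out[[length(out) + 1L]] <- resample_oriented(volume, ctr, diag(3), box)
  }
  n_dropped <- nrow(table) - length(kept)
  if (n_dropped > 0)
    log_run_event("extract_subvolumes", n_dropped = n_dropped,
                  n_kept = length(kept), box = box)
  attr(out, "kept") <- kept
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Rotate a subvolume so the filament axis lies along +z
#'
#' Applies the minimal rotation taking the segment tangent onto +z (the
#' in-plane azimuth is set to 0 by this convention; azimuth is searched
#' during 2D alignment).
#'
#' @param subvolume a `tomo_volume`.
#' @param tangent length-3 non-zero direction of the filament at the
#'   segment center (any frame-consistent units).
#' @return rotated `tomo_volume`.
#' @export
orient_to_axis <- function(subvolume, tangent) {
  stopifnot_volume(subvolume)
  if (sqrt(sum(tangent^2)) == 0) stop("tangent must be non-zero")
  R <- rotation_between(tangent, c(0, 0, 1))
  rotate_volume(subvolume, R)
}

# Soft-edged disc image (2D cylinder cross-section) used as the featureless
# centering reference; radius in Angstrom.
disc_image <- function(dm, voxel, radius, edge = 2 * voxel) {
  cx <- (dm[1] - 1) / 2; cy <- (dm[2] - 1) / 2
  r <- sqrt(outer(((0:(dm[1] - 1)) - cx)^2, ((0:(dm[2] - 1)) - cy)^2, `+`)) *
    voxel
  m <- 0.5 * (1 + cos(pi * (r - radius) / edge))
  m[r <= radius] <- 1
  m[r >= radius + edge] <- 0
  m
}

# circular cross-correlation peak of two equally sized 2D images; returns
# the signed integer displacement of `img` relative to `ref` plus a
# parabolic sub-pixel correction.
cc_peak_2d <- function(img, ref, max_shift_px = Inf) {
  a <- img - mean(img)
  b <- ref - mean(ref)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  n <- dim(cc)
  sx <- ((0:(n[1] - 1) + n[1] / 2) %% n[1]) - n[1] / 2
  sy <- ((0:(n[2] - 1) + n[2] / 2) %% n[2]) - n[2] / 2
  ok <- outer(abs(sx) <= max_shift_px, abs(sy) <= max_shift_px)
  cc[!ok] <- -Inf
  w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  peak <- c(sx[w[1]], sy[w[2]])
  # parabolic refinement per axis
  sub <- numeric(2)
  for (ax in 1:2) {
    i <- w[ax]
    n_ax <- n[ax]
    im <- ((i - 2) %% n_ax) + 1
    ip <- (i %% n_ax) + 1
    v <- if (ax == 1) c(cc[im, w[2]], cc[i, w[2]], cc[ip, w[2]])
         else c(cc[w[1], im], cc[w[1], i], cc[w[1], ip])
    den <- v[1] - 2 * v[2] + v[3]
    if (is.finite(den) && den < 0) sub[ax] <- 0.5 * (v[1] - v[3]) / den
  }
  list(shift = peak + pmax(pmin(sub, 0.5), -0.5), score = max(cc))
}

#' Center an axis-aligned segment on a featureless cylinder
#'
#' Translation-only alignment in x and y that maximizes the real-space
#' cross-correlation of the z-projected segment with a smooth disc of the
#' given radius (the cross-section of a featureless cylinder reference);
#' the z shift is fixed to 0. The default 40 A radius is a package default
#' for an actin-like filament.
#'
#' @param subvolume an axis-aligned segment (`orient_to_axis` output).
#' @param cylinder_radius cylinder radius in Angstrom.
#' @param max_shift largest allowed shift in Angstrom (default quarter box).
#' @return list with `shift` (the measured xy displacement of the filament
#'   from the box center, Angstrom) and `volume` (the re-centered segment).
#' @export
center_on_cylinder <- function(subvolume, cylinder_radius = 40,
                               max_shift = NULL) {
  stopifnot_volume(subvolume)
  d <- dim(subvolume$data)
  vx <- subvolume$voxel_size
  if (is.null(max_shift)) max_shift <- d[1] * vx / 4
  proj <- rowSums(subvolume$data, dims = 2) / d[3]
  if (stats::sd(proj) == 0) {
    warning("flat subvolume: returning zero shift")
    return(list(shift = c(0, 0), volume = subvolume))
  }
  ref <- disc_image(d[1:2], vx, cylinder_radius)
  pk <- cc_peak_2d(proj, ref, max_shift_px = max_shift / vx)
  shift <- pk$shift * vx
  recentered <- rotate_volume(subvolume, diag(3),
                              shift = c(-shift[1], -shift[2], 0))
  list(shift = shift, volume = recentered)
}
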