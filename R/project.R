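#' 2D projection stack
#'
#' Images are stored as a 3D array `(n_axial, n_transverse, n_images)`:
#' rows run along the filament axis, columns across it. `meta` carries one
#' row per image: provenance (`particle_id`, `filament_id`), and after
#' alignment the azimuth `rot` (degrees about the helical axis), in-plane
#' angle `psi` (degrees; values near 180 indicate the opposite polarity
#' branch), shifts in Angstrom and the normalized cross-correlation
#' `score`.
#'
#' @param images 3D numeric array of images.
#' @param pixel_size pixel size in Angstrom.
#' @param meta data.frame with one row per image.
#' @return a `projection_stack`.
#' @export
projection_stack <- function(images, pixel_size, meta = NULL) {
  stopifnot(length(dim(images)) == 3L)
  if (is.null(meta))
    meta <- data.frame(particle_id = seq_len(dim(images)[3]))
  if (nrow(meta) != dim(images)[3])
    stop("meta must have one row per image")
  structure(list(images = images, pixel_size = pixel_size, meta = meta),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<projection_stack> %d images of %d x %d px @ %.3f A/px\n",
              d[3], d[1], d[2], x$pixel_size))
  invisible(x)
}

n_images <- function(stack) dim(stack$images)[3]

#' Project axis-aligned segments into 2D
#'
#' Each subvolume (filament along +z after [orient_to_axis()]) is rotated
#' 90 degrees so the filament lies in the image plane and the central slab
#' (a fraction of the box depth, default 1/3 to exclude neighboring
#' density) is summed along the viewing direction, yielding one 2D image
#' per segment with the filament along the image rows.
#'
#' @param subvolumes list of axis-aligned, centered `tomo_volume`s.
#' @param slab_fraction fraction of the box used as the projected slab,
#'   in (0, 1].
#' @param meta optional per-segment metadata (one row per subvolume).
#' @return a [projection_stack()].
#' @export
project_segments <- function(subvolumes, slab_fraction = 1 / 3, meta = NULL) {
  if (slab_fraction <= 0 || slab_fraction > 1)
    stop("slab_fraction must be in (0, 1]")
  if (!length(subvolumes)) stop("no subvolumes to project")
  d <- dim(subvolumes[[1]]$data)
  vx <- subvolumes[[1]]$voxel_size
  slab_half <- slab_fraction * d[2] / 2
  imgs <- array(0, c(d[3], d[1], length(subvolumes)))
  for (i in seq_along(subvolumes))
    imgs[, , i] <- cpp_project_z(subvolumes[[i]]$data, 0, slab_half)
  projection_stack(imgs, vx, meta)
}

# Separable raised-cosine (Tukey) apodization window; tapers the outer
# `taper` pixels of each edge so that density running off the box faces
# cannot dominate shift scores.
tukey2d <- function(na, nt, taper = 6) {
  ramp <- function(n) {
    w <- rep(1, n)
    t <- min(taper, floor(n / 4))
    if (t > 0) {
      up <- 0.5 * (1 - cos(pi * (seq_len(t)) / (t + 1)))
      w[seq_len(t)] <- up
      w[n + 1 - seq_len(t)] <- up
    }
    w
  }
  outer(ramp(na), ramp(nt))
}

# window + zero-mean + unit-norm, shared by images and references
normalize_image <- function(img, window) {
  img <- img * window
  img <- img - mean(img)
  nrm <- sqrt(sum(img^2))
  if (nrm > 0) img / nrm else img
}

# Bank of reference projections over an azimuth x in-plane-angle grid.
# Returns a list with the image array (na, nt, n), and the rot/psi of each.
reference_projections <- function(reference, rots, psis, window = NULL) {
  combos <- expand.grid(psi = psis, rot = rots)
  d <- dim(reference$data)
  if (is.null(window)) window <- tukey2d(d[3], d[1])
  imgs <- array(0, c(d[3], d[1], nrow(combos)))
  i <- 0
  for (rot in rots) {
    P <- cpp_project_z(reference$data, deg2rad(rot), -1)
    for (psi in psis) {
      i <- i + 1
      img <- if (psi == 0) P else cpp_transform2d(P, deg2rad(psi), c(0, 0))
      imgs[, , i] <- normalize_image(img, window)
    }
  }
  list(images = imgs, rot = combos$rot, psi = combos$psi)
}

#' Align a projection stack against a 3D reference by projection matching
#'
#' Reference projections are generated at azimuths `0 ... 360` degrees in
#' `rot_step` steps about the helical axis; each is rotated in-plane over
#' `+/- psi_range` about 0 and (if `polarity_search`) about 180 degrees —
#' the opposite-polarity branch. Every image is scored against every
#' reference over integer-pixel shifts (axial shift capped at
#' `max_axial_shift`, transverse at `max_shift`) by normalized
#' cross-correlation; the best entry, with parabolic sub-pixel shift
#' refinement, is recorded in the stack metadata.
#'
#' @param stack a [projection_stack()].
#' @param reference a `tomo_volume` with the filament along +z. Low-pass
#'   filter it before calling (e.g. to 60 A for an external reference).
#' @param rot_step azimuthal step in degrees.
#' @param psi_range,psi_step in-plane search range/step in degrees.
#' @param max_shift transverse shift cap in Angstrom.
#' @param max_axial_shift axial shift cap in Angstrom (typically rise/2).
#' @param polarity how the opposite-polarity (psi + 180) branch is
#'   searched: `"filament"` (default) scores both branches and commits
#'   every segment of a filament to the branch with the better total score
#'   — polarity is a property of the filament, and branch-inconsistent
#'   segments would back-project mutually flipped images; `"segment"`
#'   lets every segment choose independently; `"none"` searches only the
#'   psi ~ 0 branch. Per-segment branch preferences are always recorded in
#'   `polarity_flag` for [vote_polarity()].
#' @param axial_prior_sd,trans_prior_sd,prior_weight weak Gaussian prior
#'   on shifts: the score is penalized by
#'   `prior_weight * shift^2 / (2 * sd^2)` per axis, so that
#'   shift-degenerate matches (smooth low-pass filament images) stay
#'   anchored at the trace-derived centers instead of drifting along the
#'   azimuth/axial degeneracy ridge; real image features easily override
#'   it. The axial prior is stronger because segment centers derive from
#'   the traced centerline.
#' @return the stack with `rot`, `psi`, `shift_axial`, `shift_trans`,
#'   `score` and `polarity_flag` columns filled in.
#' @export
align_2d <- function(stack, reference, rot_step = 4, psi_range = 15,
                     psi_step = 5, max_shift = 16, max_axial_shift = 14,
                     polarity = c("filament", "segment", "none"),
                     axial_prior_sd = 14, trans_prior_sd = 8,
                     prior_weight = 0.01) {
  if (!n_images(stack)) return(stack)
  polarity <- match.arg(polarity)
  if (polarity == "filament" && is.null(stack$meta$filament_id))
    polarity <- "segment"
  stopifnot_volume(reference)
  vx <- stack$pixel_size
  rots <- seq(0, 360 - rot_step, by = rot_step)
  po <- seq(-psi_range, psi_range, by = psi_step)
  d <- dim(stack$images)
  win <- tukey2d(d[1], d[2])
  dzs <- seq(-floor(max_axial_shift / vx), floor(max_axial_shift / vx))
  dxs <- seq(-floor(max_shift / vx), floor(max_shift / vx))
  imgs <- stack$images
  for (i in seq_len(d[3]))
    imgs[, , i] <- imgs[, , i] - mean(imgs[, , i])
  pz <- prior_weight * vx^2 / (2 * axial_prior_sd^2)
  px <- prior_weight * vx^2 / (2 * trans_prior_sd^2)

  run_branch <- function(psis) {
    bank <- reference_projections(reference, rots, psis, window = win)
    for (i in seq_len(dim(bank$images)[3]))
      bank$images[, , i] <- bank$images[, , i] * win
    res <- cpp_cc_align(imgs, bank$images, as.integer(dzs), as.integer(dxs),
                        win * win, penalty_z = pz, penalty_x = px)
    sub <- function(p, q) {
      den <- p - 2 * res[, 4] + q
      out <- ifelse(is.finite(den) & den < 0, 0.5 * (p - q) / den, 0)
      pmax(pmin(out, 0.5), -0.5)
    }
    data.frame(rot = bank$rot[res[, 1]], psi = bank$psi[res[, 1]],
               shift_axial = (res[, 2] + sub(res[, 5], res[, 6])) * vx,
               shift_trans = (res[, 3] + sub(res[, 7], res[, 8])) * vx,
               score = res[, 4])
  }

  up <- run_branch(po)
  if (polarity == "none") {
    sel <- up
    flag <- rep("up", nrow(up))
  } else {
    down <- run_branch(po + 180)
    flag <- ifelse(up$score >= down$score, "up", "down")
    if (polarity == "segment") {
      use_down <- flag == "down"
    } else {
      fids <- stack$meta$filament_id
      use_down <- logical(nrow(up))
      for (f in unique(fids)) {
        idx <- fids == f
        use_down[idx] <- sum(down$score[idx]) > sum(up$score[idx])
      }
    }
    sel <- up
    sel[use_down, ] <- down[use_down, ]
  }
  stack$meta$rot <- sel$rot
  stack$meta$psi <- sel$psi
  stack$meta$shift_axial <- sel$shift_axial
  stack$meta$shift_trans <- sel$shift_trans
  stack$meta$score <- sel$score
  stack$meta$polarity_flag <- flag
  stack
}

# Local (per-image) re-alignment around each image's current rot/psi at
# finer steps; same scoring as align_2d.
align_2d_local <- function(stack, reference, rot_range = 6, rot_step = 2,
                           psi_range = 6, psi_step = 2, max_shift = 11,
                           max_axial_shift = 14, axial_prior_sd = 14,
                           trans_prior_sd = 8, prior_weight = 0.01) {
  if (!n_images(stack)) return(stack)
  vx <- stack$pixel_size
  dzs <- seq(-floor(max_axial_shift / vx), floor(max_axial_shift / vx))
  dxs <- seq(-floor(max_shift / vx), floor(max_shift / vx))
  dro <- seq(-rot_range, rot_range, by = rot_step)
  dps <- seq(-psi_range, psi_range, by = psi_step)
  win <- tukey2d(dim(stack$images)[1], dim(stack$images)[2])
  meta <- stack$meta
  # group images by (rot, psi) prior so each bank is built once
  key <- paste(meta$rot, meta$psi)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    rots <- (meta$rot[idx[1]] + dro) %% 360
    psis <- meta$psi[idx[1]] + dps
    bank <- reference_projections(reference, rots, psis, window = win)
    for (i in seq_len(dim(bank$images)[3]))
      bank$images[, , i] <- bank$images[, , i] * win
    imgs <- stack$images[, , idx, drop = FALSE]
    for (i in seq_along(idx))
      imgs[, , i] <- imgs[, , i] - mean(imgs[, , i])
    res <- cpp_cc_align(imgs, bank$images, as.integer(dzs), as.integer(dxs),
                        win * win,
                        penalty_z = prior_weight * vx^2 / (2 * axial_prior_sd^2),
                        penalty_x = prior_weight * vx^2 / (2 * trans_prior_sd^2))
    subz <- ifelse(res[, 5] - 2 * res[, 4] + res[, 6] < 0,
                   0.5 * (res[, 5] - res[, 6]) /
                     (res[, 5] - 2 * res[, 4] + res[, 6]), 0)
    subx <- ifelse(res[, 7] - 2 * res[, 4] + res[, 8] < 0,
                   0.5 * (res[, 7] - res[, 8]) /
                     (res[, 7] - 2 * res[, 4] + res[, 8]), 0)
    meta$rot[idx] <- bank$rot[res[, 1]]
    meta$psi[idx] <- bank$psi[res[, 1]]
    meta$shift_axial[idx] <- (res[, 2] + pmax(pmin(subz, .5), -.5)) * vx
    meta$shift_trans[idx] <- (res[, 3] + pmax(pmin(subx, .5), -.5)) * vx
    meta$score[idx] <- res[, 4]
  }
  meta$polarity_flag <- ifelse(cos(deg2rad(meta$psi)) >= 0, "up", "down")
  stack$meta <- meta
  stack
}

# Resample every image into the canonical reference frame (undo psi and
# shift), so that image i approximates the reference projection at its
# azimuth rot_i.
canonicalize_stack <- function(stack) {
  m <- stack$meta
  if (is.null(m$psi)) stop("stack is not aligned")
  vx <- stack$pixel_size
  out <- stack$images
  for (i in seq_len(n_images(stack))) {
    out[, , i] <- cpp_transform2d(stack$images[, , i], -deg2rad(m$psi[i]),
                                  c(m$shift_axial[i], m$shift_trans[i]) / vx)
  }
  stack$images <- out
  stack
}
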