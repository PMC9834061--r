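# Shared fixtures, all generated in code at test time.

# straight trace through the center of a box, along +z
z_trace <- function(box = 64, voxel = 5.36, margin = 0) {
  ctr <- (box - 1) / 2 * voxel
  filament_trace(cbind(ctr, ctr, seq(margin, (box - 1) * voxel - margin,
                                     length.out = 5)))
}

# ribosome-like two-species fixture: gaussian core with / without a
# solid-sphere surface density (expansion-segment mimic, ~8000 A^3)
two_species_models <- function(voxel = 4.51, box = 48, core_diam = 150,
                               blob_radius = 12.4, blob_offset = c(80, 0, 0)) {
  core <- make_subunit_model("gaussian_blob", core_diam, voxel, box = box)
  blob <- make_solid_sphere(blob_radius, voxel)
  d <- dim(core$data)
  p <- matrix(blob_offset / voxel + (d - 1) / 2, 1)
  extra <- tomohelix:::cpp_render_subunits(as.integer(d), blob$data, p,
                               as.numeric(array(diag(3), c(3, 3, 1))))
  list(A = core,
       B = new_volume(core$data + extra, voxel),
       blob_center = (d - 1) / 2 * voxel + blob_offset,
       blob_volume = 4 / 3 * pi * blob_radius^3)
}

# mixed two-species particle set at random known orientations, with the
# missing wedge and noise applied; balanced labels
two_species_particles <- function(n = 40, snr = 0.3, seed = 5,
                                  geometry = acquisition_geometry(),
                                  noise = TRUE) {
  mod <- two_species_models()
  set.seed(seed)
  parts <- vector("list", n)
  labs <- character(n)
  tab <- NULL
  for (i in seq_len(n)) {
    sp <- if (i %% 2) mod$A else mod$B
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- tomohelix:::quat_to_matrix(q)
    eul <- matrix_to_euler(R)
    v <- apply_missing_wedge(rotate_volume(sp, R), geometry)
    if (noise) v <- add_noise(v, snr, seed = 1000 + i)
    parts[[i]] <- v
    labs[i] <- if (i %% 2) "A" else "B"
    tab <- rbind(tab, data.frame(euler_phi = eul[1], euler_theta = eul[2],
                                 euler_psi = eul[3], shift_x = 0,
                                 shift_y = 0, shift_z = 0))
  }
  list(particles = parts, labels = labs, table = tab, models = mod,
       geometry = geometry)
}

# label-permutation-invariant two-class purity
class_purity <- function(assignments, labels) {
  max(mean((assignments == 1) == (labels == labels[1])),
      mean((assignments == 2) == (labels == labels[1])))
}

expect_angle_close <- function(a, b, tol, mod = 360) {
  d <- (a - b) %% mod
  d <- min(d, mod - d)
  expect_lt(d, tol)
}
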