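# asymmetric fixture for pose recovery (two unequal surface densities kill
# every rotational degeneracy); small box keeps the search affordable
asym_model <- function(voxel = 6, box = 32) {
  core <- make_subunit_model("gaussian_blob", 100, voxel, box = box)
  b1 <- make_solid_sphere(20, voxel)
  b2 <- make_solid_sphere(15, voxel)
  d <- dim(core$data)
  addb <- function(base, blob, off) {
    p <- matrix(off / voxel + (d - 1) / 2, 1)
    base + tomohelix:::cpp_render_subunits(as.integer(d), blob$data, p,
                                           as.numeric(array(diag(3),
                                                            c(3, 3, 1))))
  }
  new_volume(addb(addb(core$data, b1, c(55, 0, 0)), b2, c(0, 48, 26)),
             voxel)
}

test_that("sub-tomogram alignment recovers a planted rigid pose", {
  ref <- asym_model()
  part <- rotate_volume(ref, euler_to_matrix(20, 35, 50), shift = c(12, -6, 0))
  al <- align_subtomograms(list(part), ref, angle_step = 15,
                           local_refine = 4, max_shift = 18)
  Rt <- euler_to_matrix(20, 35, 50)
  Rh <- euler_to_matrix(al$euler_phi, al$euler_theta, al$euler_psi)
  ang <- acos((min(sum(diag(t(Rh) %*% Rt)), 3) - 1) / 2) * 180 / pi
  expect_lt(ang, 15 / 2^4 + 1.5)             # within the finest grid level
  expect_lt(max(abs(c(al$shift_x - 12, al$shift_y + 6, al$shift_z))), 6 + 1e-9)
  expect_gt(al$score, 0.98)

  # duplicated particles get identical alignments
  al2 <- align_subtomograms(list(part, part), ref, angle_step = 30,
                            local_refine = 1, max_shift = 18)
  expect_identical(al2[1, -1], structure(al2[2, -1], row.names = 1L,
                                         class = "data.frame"))
  # empty input, empty output
  expect_equal(nrow(align_subtomograms(list(), ref)), 0L)
})

test_that("noise scores below a matched particle", {
  ref <- asym_model()
  part <- rotate_volume(ref, euler_to_matrix(10, 20, 30))
  set.seed(3)
  noise <- new_volume(array(rnorm(length(ref$data)), dim(ref$data)),
                      ref$voxel_size)
  al <- align_subtomograms(list(part, noise), ref, angle_step = 30,
                           local_refine = 1, max_shift = 12)
  expect_gt(al$score[1], al$score[2] + 0.2)
})

test_that("averaging re-poses a single particle and ignores ordering", {
  ref <- asym_model()
  eulers <- rbind(c(15, 40, 70), c(200, 120, 10), c(80, 60, 300))
  parts <- lapply(seq_len(3), function(i)
    rotate_volume(ref, euler_to_matrix(eulers[i, 1], eulers[i, 2],
                                       eulers[i, 3])))
  tab <- data.frame(euler_phi = eulers[, 1], euler_theta = eulers[, 2],
                    euler_psi = eulers[, 3], shift_x = 0, shift_y = 0,
                    shift_z = 0)
  # N = 1: the average is the particle re-posed
  a1 <- average_subtomograms(parts[1], tab[1, , drop = FALSE])
  mask <- tomohelix:::sphere_mask(dim(ref$data), ref$voxel_size, 70) > 0.5
  expect_gt(vol_correlation(a1$data, ref$data, mask), 0.98)
  # permutation invariance
  avg <- average_subtomograms(parts, tab)
  perm <- c(3, 1, 2)
  avg2 <- average_subtomograms(parts[perm], tab[perm, , drop = FALSE])
  expect_equal(avg$data, avg2$data, tolerance = 1e-12)
  expect_gt(vol_correlation(avg$data, ref$data, mask), 0.97)
  expect_error(average_subtomograms(list(), tab), "zero particles")
})

test_that("random wedge orientations leave no uncovered Fourier voxel", {
  d <- rep(24, 3)
  geom <- acquisition_geometry()
  wmask <- tomohelix:::wedge_sampling_mask(d, geom)
  wvol <- new_volume(tomohelix:::fftshift3(array(as.numeric(wmask), d)), 1)
  set.seed(21)
  cov <- array(0, d)
  for (i in 1:20) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- tomohelix:::quat_to_matrix(q)
    cov <- cov + (tomohelix:::fftshift3(rotate_volume(wvol, t(R))$data) >= 0.5)
  }
  # ignore the few voxels beyond the Nyquist sphere (never rotated inside)
  kr <- tomohelix:::kradius3(d, 1)
  expect_true(all(cov[kr <= 0.45] > 0))
})

test_that("wedge-averaged phantoms reproduce the phantom", {
  ref <- asym_model()
  geom <- acquisition_geometry()
  set.seed(17)
  n <- 12
  parts <- list(); tab <- NULL
  for (i in seq_len(n)) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- tomohelix:::quat_to_matrix(q)
    eul <- matrix_to_euler(R)
    parts[[i]] <- apply_missing_wedge(rotate_volume(ref, R), geom)
    tab <- rbind(tab, data.frame(euler_phi = eul[1], euler_theta = eul[2],
                                 euler_psi = eul[3], shift_x = 0,
                                 shift_y = 0, shift_z = 0))
  }
  avg <- average_subtomograms(parts, tab, geom)
  mask <- tomohelix:::sphere_mask(dim(ref$data), ref$voxel_size, 70) > 0.5
  expect_gt(vol_correlation(avg$data, ref$data, mask), 0.95)
})

test_that("rigid-body fitting recovers identity and planted rotations", {
  ref <- asym_model()
  fid <- fit_reference(ref, ref, angle_step = 30)
  expect_gt(fid$correlation, 0.999)
  expect_lt(sqrt(sum(fid$shift^2)), 3)

  rot <- rotate_volume(ref, tomohelix:::rot_z(25))
  f <- fit_reference(rot, ref, angle_step = 15)
  expect_gt(f$correlation, 0.98)
  mask <- tomohelix:::sphere_mask(dim(ref$data), ref$voxel_size, 70) > 0.5
  expect_gt(vol_correlation(f$fitted$data, rot$data, mask), 0.98)

  set.seed(4)
  noise <- new_volume(array(rnorm(length(ref$data)), dim(ref$data)),
                      ref$voxel_size)
  expect_error(fit_reference(noise, ref, angle_step = 45,
                             min_correlation = 0.3), "no fit")
})

test_that("fit_reference inverts a transform within the search resolution", {
  ref <- asym_model()
  R <- euler_to_matrix(12, 18, -9)
  moved <- rotate_volume(ref, R, shift = c(6, 0, -6))
  f <- fit_reference(moved, ref, angle_step = 15)
  mask <- tomohelix:::sphere_mask(dim(ref$data), ref$voxel_size, 70) > 0.5
  expect_gt(vol_correlation(f$fitted$data, moved$data, mask), 0.98)
})

test_that("difference density finds planted blobs and nothing else", {
  mod <- two_species_models()
  # identity: empty report
  dd0 <- difference_density(mod$A, mod$A)
  expect_equal(nrow(dd0), 0L)
  # planted 8000 A^3 surface sphere: exactly one blob, centroid within
  # 2 voxels, volume within 25%
  dd <- difference_density(mod$B, mod$A)
  expect_equal(nrow(dd), 1L)
  cen <- c(dd$centroid_x, dd$centroid_y, dd$centroid_z)
  expect_lt(sqrt(sum((cen - mod$blob_center)^2)), 2 * 4.51)
  expect_lt(abs(dd$volume - mod$blob_volume) / mod$blob_volume, 0.25)

  # two touching densities merge into a single 26-connected component
  vx <- 4.51
  core <- mod$A
  b <- make_solid_sphere(10, vx)
  d <- dim(core$data)
  addb <- function(base, off) {
    p <- matrix(off / vx + (d - 1) / 2, 1)
    base + tomohelix:::cpp_render_subunits(as.integer(d), b$data, p,
                                           as.numeric(array(diag(3),
                                                            c(3, 3, 1))))
  }
  two <- new_volume(addb(addb(core$data, c(78, 0, 0)), c(78, 14, 0)), vx)
  ddm <- difference_density(two, core)
  expect_equal(nrow(ddm), 1L)
})

test_that("3D connected-component labelling uses 26-connectivity", {
  m <- array(0L, c(5, 5, 5))
  m[1, 1, 1] <- 1L
  m[2, 2, 2] <- 1L   # diagonal neighbor: same component under 26-conn
  m[5, 5, 5] <- 1L
  lab <- tomohelix:::cpp_label3d(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_false(lab[5, 5, 5] == lab[1, 1, 1])
})
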