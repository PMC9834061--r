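# shared noise-free fixture: two-stranded filament along z at the refined
# study parameters (rise 27.9 A, twist -167.7 deg)
ref_truth <- make_helical_reference(helical_params(27.9, -167.7), 64, 5.36)

test_that("helical parameter refinement recovers the generative values", {
  coarse <- refine_helical_params(ref_truth,
                                  prior = helical_params(27.5, -166.7),
                                  rise_step = 0.5, twist_step = 0.5)
  fine <- refine_helical_params(
    ref_truth, prior = helical_params(27.5, -166.7),
    rise_range = coarse$params$rise + c(-0.6, 0.6), rise_step = 0.1,
    twist_range = coarse$params$twist + c(-1.2, 1.2), twist_step = 0.1)
  expect_lt(abs(fine$params$rise - 27.9), 0.1 + 1e-9)
  expect_lt(abs(fine$params$twist - -167.7), 0.1 + 1e-9)
})

test_that("a featureless cylinder is reported as unresolved", {
  cyl <- new_volume(array(tomohelix:::cylinder_mask(rep(48, 3), 5.36, 40),
                          rep(48, 3)), 5.36)
  expect_error(refine_helical_params(cyl, rise_step = 1, twist_step = 2),
               "unresolved")
})

test_that("symmetrization fixes symmetric maps and is idempotent", {
  p <- helical_params(27.9, -167.7)
  s1 <- symmetrize_helix(ref_truth, p)
  mask <- tomohelix:::cylinder_mask(rep(64, 3), 5.36, 50, z_fraction = 0.5) > 0.5
  expect_gt(vol_correlation(s1$data, ref_truth$data, mask), 0.999)
  # idempotence holds up to the smoothing of one extra trilinear pass
  s2 <- symmetrize_helix(s1, p)
  expect_lt(max(abs(s2$data - s1$data)) / max(abs(s1$data)), 0.08)
  expect_gt(vol_correlation(s2$data, s1$data, mask), 0.999)
  expect_error(symmetrize_helix(ref_truth, helical_params(2, 10)),
               "unresolvable")
})

test_that("symmetrizing pure noise averages its variance down", {
  set.seed(8)
  nz <- new_volume(array(rnorm(64^3), rep(64, 3)), 5.36)
  s <- symmetrize_helix(nz, helical_params(27.9, -167.7),
                        z_extent_fraction = 0.6)
  k <- diff(attr(s, "k_range")) + 1
  mask <- tomohelix:::cylinder_mask(rep(64, 3), 5.36, 50,
                                    z_fraction = 0.5) > 0.5
  ratio <- stats::var(nz$data[mask]) / stats::var(s$data[mask])
  # variance reduced at least in proportion to the number of averaged
  # copies (interpolation smoothing reduces it further)
  expect_gt(ratio, 0.7 * k)
  expect_lt(ratio, 5 * k)
})

test_that("projections show the filament band and the rise layer line", {
  sub <- make_subunit_model("gaussian_blob", 18, 5.36)
  tr <- z_trace(64, 5.36)
  rf <- render_filament(tr, helical_params(27.9, -167.7), sub,
                        dim = rep(64, 3), voxel_size = 5.36,
                        two_strands = TRUE, helix_radius = 12)
  stack <- project_segments(list(rf$volume), slab_fraction = 1)
  img <- stack$images[, , 1]
  # band along the axial rows: transverse profile concentrated at center
  tp <- colSums(abs(img))
  expect_gt(tp[32], 3 * mean(tp[c(1:8, 57:64)]))
  # power spectrum along the axis peaks near 1/27.9
  ap <- rowSums(img[, 28:37])
  ps <- abs(stats::fft(ap - mean(ap)))^2
  fz <- tomohelix:::fft_freqs(64, 5.36)
  sel <- which(fz > 0.02 & fz < 0.06)
  pk <- sel[which.max(ps[sel])]
  expect_lt(abs(1 / fz[pk] - 27.9), 3)

  # a blank subvolume projects to a blank image
  blank <- new_volume(array(0, rep(16, 3)), 5.36)
  expect_equal(max(abs(project_segments(list(blank))$images)), 0)
  expect_error(project_segments(list(blank), slab_fraction = 0), "slab")
  # slab_fraction = 1 equals the full projection
  full <- tomohelix:::cpp_project_z(rf$volume$data, 0, -1)
  expect_equal(stack$images[, , 1], full, tolerance = 1e-10)
})

test_that("projection matching recovers planted poses up to C2 symmetry", {
  refl <- lowpass_volume(ref_truth, 35)
  # with the polarity branch fixed, the pose is identifiable up to the
  # exact C2 symmetry of the two-start filament (rot modulo 180)
  cases <- list(c(5, 2, -1), c(-10, 1, 2), c(12, -2, 0))
  for (cs in cases) {
    img <- tomohelix:::cpp_transform2d(
      tomohelix:::cpp_project_z(refl$data, 48 * pi / 180, -1),
      cs[1] * pi / 180, c(0, 0))
    img <- tomohelix:::cpp_transform2d(img, 0, c(-cs[2], -cs[3]))
    stk <- projection_stack(array(img, c(64, 64, 1)), 5.36)
    al <- align_2d(stk, refl, rot_step = 4, psi_range = 15, psi_step = 5,
                   max_shift = 22, max_axial_shift = 22,
                   polarity = "none")
    # rot within two grid steps; the axial shift trades off continuously
    # against rot along the helical screw, so it is bounded by the ridge
    # extent (half a rise); the transverse shift has no such degeneracy
    expect_angle_close(al$meta$rot, 48, 8 + 1e-9, mod = 180)
    expect_angle_close(al$meta$psi, cs[1], 5 + 1e-9)
    expect_lt(abs(al$meta$shift_axial / 5.36 - cs[2]), 27.9 / 2 / 5.36 + 1e-9)
    expect_lt(abs(al$meta$shift_trans / 5.36 - cs[3]), 1.5)
    expect_gt(al$meta$score, 0.9)
  }
  # an end-flipped view is matched on the opposite-polarity branch; the
  # flipped pose family is score-equivalent, so assert the branch and the
  # quality of the match rather than a unique pose
  imgf <- tomohelix:::cpp_transform2d(
    tomohelix:::cpp_project_z(refl$data, 48 * pi / 180, -1),
    185 * pi / 180, c(0, 0))
  stkf <- projection_stack(array(imgf, c(64, 64, 1)), 5.36)
  alf <- align_2d(stkf, refl, rot_step = 4, psi_range = 15, psi_step = 5,
                  max_shift = 22, max_axial_shift = 22,
                  polarity = "segment")
  expect_identical(alf$meta$polarity_flag, "down")
  expect_gt(alf$meta$score, 0.9)
  # determinism: identical images get identical alignments
  img <- tomohelix:::cpp_project_z(refl$data, 72 * pi / 180, -1)
  stk2 <- projection_stack(array(rep(img, 2), c(64, 64, 2)), 5.36)
  al2 <- align_2d(stk2, refl, polarity = "segment")
  expect_identical(al2$meta$rot[1], al2$meta$rot[2])
  expect_identical(al2$meta$shift_axial[1], al2$meta$shift_axial[2])
  # empty stack passes through
  empty <- projection_stack(array(0, c(8, 8, 0)),
                            5.36, data.frame(particle_id = integer(0)))
  expect_equal(tomohelix:::n_images(align_2d(empty, refl)), 0L)
})

test_that("psi-restricted search cannot beat the true azimuth", {
  refl <- lowpass_volume(ref_truth, 35)
  img <- tomohelix:::cpp_project_z(refl$data, 48 * pi / 180, -1)
  stk <- projection_stack(array(img, c(64, 64, 1)), 5.36)
  al <- align_2d(stk, refl, rot_step = 4, psi_range = 0, psi_step = 5,
                 max_shift = 11, max_axial_shift = 11, polarity = "none")
  expect_equal(al$meta$psi, 0)
  expect_angle_close(al$meta$rot, 48, 4 + 1e-9, mod = 180)
})

test_that("2D classification separates distinct patterns and is seeded", {
  set.seed(6)
  a <- matrix(0, 32, 32); a[10:22, 14:18] <- 1
  b <- matrix(0, 32, 32); b[5:8, 1:32] <- 1
  imgs <- array(0, c(32, 32, 12))
  for (i in 1:12) imgs[, , i] <- (if (i %% 2) a else b) +
      0.05 * matrix(rnorm(1024), 32)
  stk <- projection_stack(imgs, 5)
  cl <- classify_2d(stk, k = 2, seed = 9)
  expect_equal(class_purity(cl$assignments, rep(c("a", "b"), 6)), 1)
  cl2 <- classify_2d(stk, k = 2, seed = 9)
  expect_identical(cl$assignments, cl2$assignments)
  # k = 1 is the mean of the (normalized) stack
  cl1 <- classify_2d(stk, k = 1, seed = 1)
  norm1 <- function(x) { x <- x - mean(x); x / sqrt(sum(x^2)) }
  m <- 0
  for (i in 1:12) m <- m + norm1(imgs[, , i]) / 12
  expect_gt(stats::cor(as.vector(cl1$averages[, , 1]), as.vector(norm1(m))),
            0.999)
  expect_error(classify_2d(stk, k = 50), "exceeds")
})

test_that("weighted back-projection reconstructs a phantom faithfully", {
  rots <- seq(0, 356, by = 4)
  imgs <- array(0, c(64, 64, length(rots)))
  for (i in seq_along(rots))
    imgs[, , i] <- tomohelix:::cpp_project_z(ref_truth$data,
                                             rots[i] * pi / 180, -1)
  stk <- projection_stack(imgs, 5.36)
  stk$meta$rot <- rots
  rec <- reconstruct_3d(stk, 64, 64, min_images = 1)
  mask <- tomohelix:::cylinder_mask(rep(64, 3), 5.36, 55,
                                    z_fraction = 0.8) > 0.5
  r60 <- lowpass_volume(rec, 60)
  p60 <- lowpass_volume(ref_truth, 60)
  expect_gt(vol_correlation(r60$data, p60$data, mask), 0.95)

  # duplicating every image rescales but does not change the map
  stk2 <- projection_stack(array(rep(imgs, 2), c(64, 64, 2 * length(rots))),
                           5.36)
  stk2$meta$rot <- rep(rots, 2)
  rec2 <- reconstruct_3d(stk2, 64, 64, min_images = 1)
  expect_gt(vol_correlation(rec2$data, rec$data), 0.9999)

  # a single image gives a low-confidence smeared volume
  stk1 <- projection_stack(imgs[, , 1, drop = FALSE], 5.36)
  stk1$meta$rot <- rots[1]
  expect_warning(r1 <- reconstruct_3d(stk1, 64, 64, min_images = 50),
                 "low-confidence")
  expect_true(attr(r1, "low_confidence"))
  expect_error(reconstruct_3d(projection_stack(array(0, c(8, 8, 0)), 5,
                                               data.frame(particle_id = integer(0)))),
               "empty")
})
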