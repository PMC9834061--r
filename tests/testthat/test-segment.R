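test_that("segment counts follow floor(L/s) + 1 and survive rigid motion", {
  tr <- filament_trace(cbind(seq(0, 321.3, length.out = 4), 0, 0))
  seg <- segment_trace(tr, 32.13)
  expect_equal(nrow(seg), 11L)          # floor(321.3 / 32.13) + 1
  expect_equal(seg$arc_position, (0:10) * 32.13, tolerance = 1e-6)

  # rigid motion of the trace leaves the count unchanged
  R <- euler_to_matrix(31, 47, 13)
  moved <- filament_trace(t(R %*% t(tr$points)) +
                            matrix(c(100, -40, 7), 4, 3, byrow = TRUE))
  expect_equal(nrow(segment_trace(moved, 32.13)), 11L)

  short <- filament_trace(cbind(c(0, 10), c(0, 0), c(0, 0)))
  expect_warning(s1 <- segment_trace(short, 32.13), "single segment")
  expect_equal(nrow(s1), 1L)
})

test_that("tangents of a semicircular trace are perpendicular to the radius", {
  th <- seq(0, pi, length.out = 36)
  tr <- filament_trace(cbind(100 * cos(th), 100 * sin(th), 0))
  seg <- segment_trace(tr, 32.13)
  ctr <- c(0, 0, 0)
  for (i in seq_len(nrow(seg))) {
    r <- c(seg$center_x[i], seg$center_y[i], seg$center_z[i]) - ctr
    tang <- c(seg$tangent_x[i], seg$tangent_y[i], seg$tangent_z[i])
    ang <- abs(90 - acos(abs(sum(r * tang)) / sqrt(sum(r^2))) * 180 / pi)
    expect_lt(ang, 2)
  }
})

test_that("subvolume extraction crops exactly at voxel centers and
           interpolates linearly between them", {
  set.seed(4)
  vol <- new_volume(array(rnorm(32^3), rep(32, 3)), 2)
  # an even box centers between voxels, so a center at a half-voxel
  # position puts every sample on the grid: equals the direct crop
  tab <- data.frame(center_x = 15.5 * 2, center_y = 15.5 * 2,
                    center_z = 15.5 * 2)
  subs <- extract_subvolumes(vol, tab, 8)
  direct <- vol$data[13:20, 13:20, 13:20]
  expect_equal(subs[[1]]$data, direct, tolerance = 1e-12)

  # half a voxel further on a linear ramp: exact average of adjacent crops
  ramp <- new_volume(array(rep(seq_len(32), times = 32 * 32), rep(32, 3)), 2)
  tabh <- data.frame(center_x = 16 * 2, center_y = 15.5 * 2,
                     center_z = 15.5 * 2)
  subh <- extract_subvolumes(ramp, tabh, 8)[[1]]
  avg <- (ramp$data[13:20, 13:20, 13:20] + ramp$data[14:21, 13:20, 13:20]) / 2
  expect_equal(subh$data, avg, tolerance = 1e-12)

  # a segment whose box does not fit is dropped and counted
  tabb <- rbind(tab, data.frame(center_x = 2, center_y = 2, center_z = 2))
  subs2 <- extract_subvolumes(vol, tabb, 8)
  expect_length(subs2, 1L)
  expect_equal(attr(subs2, "n_dropped"), 1L)
  expect_error(extract_subvolumes(vol, tab, 7), "even")
  expect_error(extract_subvolumes(vol, tab, 64), "larger")
})

test_that("orient_to_axis sends the tangent onto +z", {
  sub <- make_subunit_model("gaussian_blob", 30, 5.36)
  tr <- filament_trace(cbind(seq(20, 300, length.out = 4), 160, 160))
  rf <- render_filament(tr, helical_params(27.9, -167.7), sub,
                        dim = c(60, 60, 60), voxel_size = 5.36,
                        helix_radius = 10)
  # identity when the tangent is already +z
  v <- rf$volume
  same <- orient_to_axis(v, c(0, 0, 1))
  expect_gt(vol_correlation(same$data, v$data), 0.999)

  # tangent +x: after orientation the maximal-variance axis is z within 2 deg
  or <- orient_to_axis(v, c(1, 0, 0))
  idx <- which(or$data > 0.3 * max(or$data), arr.ind = TRUE)
  pc <- stats::prcomp(idx)
  axis1 <- abs(pc$rotation[, 1])
  ang <- acos(axis1[3] / sqrt(sum(axis1^2))) * 180 / pi
  expect_lt(ang, 2)

  # -z tangent: axial profile reverses
  fl <- orient_to_axis(rf$volume, c(0, 0, -1))
  expect_error(orient_to_axis(v, c(0, 0, 0)), "non-zero")
  prof_f <- apply(fl$data, 3, sum)
  prof_o <- apply(v$data, 3, sum)
  expect_gt(stats::cor(prof_f, rev(prof_o)), 0.95)
})

test_that("orientation round-trips within interpolation error", {
  sub <- make_subunit_model("gaussian_blob", 40, 5.36)
  sm <- lowpass_volume(sub, 30)
  R <- tomohelix:::rotation_between(c(1, 1, 0.3), c(0, 0, 1))
  fwd <- rotate_volume(sm, R)
  back <- rotate_volume(fwd, t(R))
  mask <- tomohelix:::sphere_mask(dim(sm$data), 5.36, 30) > 0.5
  expect_gt(vol_correlation(back$data, sm$data, mask), 0.99)
})

test_that("cylinder centering recovers planted displacements", {
  sub <- make_subunit_model("gaussian_blob", 45, 5.36)
  tr <- z_trace(48, 5.36)
  rf <- render_filament(tr, helical_params(27.9, -167.7), sub,
                        dim = rep(48, 3), voxel_size = 5.36)
  v <- rf$volume
  # displace by (+3, -2) voxels and recover within 0.5 voxel
  disp <- rotate_volume(v, diag(3), shift = c(3, -2, 0) * 5.36)
  cen <- center_on_cylinder(disp, 40)
  expect_lt(max(abs(cen$shift / 5.36 - c(3, -2))), 0.5)
  # already centered: shift below half a voxel
  cen0 <- center_on_cylinder(v, 40)
  expect_lt(sqrt(sum(cen0$shift^2)) / 5.36, 0.5)
  # translation equivariance
  disp2 <- rotate_volume(v, diag(3), shift = c(2, 1, 0) * 5.36)
  cen2 <- center_on_cylinder(disp2, 40)
  expect_lt(max(abs((cen2$shift - cen0$shift) / 5.36 - c(2, 1))), 0.5)
  # flat volume: zero shift with a warning
  flat <- new_volume(array(1, rep(16, 3)), 5.36)
  expect_warning(cf <- center_on_cylinder(flat), "flat")
  expect_equal(cf$shift, c(0, 0))
})

test_that("noisy displaced filaments are still centered within a voxel", {
  sub <- make_subunit_model("gaussian_blob", 45, 5.36)
  tr <- z_trace(48, 5.36)
  rf <- render_filament(tr, helical_params(27.9, -167.7), sub,
                        dim = rep(48, 3), voxel_size = 5.36)
  hits <- 0
  for (t in 1:20) {
    noisy <- add_noise(rf$volume, 0.1, seed = 500 + t)
    disp <- rotate_volume(noisy, diag(3), shift = c(2, 0, 0) * 5.36)
    cen <- center_on_cylinder(disp, 40)
    if (max(abs(cen$shift / 5.36 - c(2, 0))) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
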