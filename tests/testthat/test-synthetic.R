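test_that("subunit models have the advertised geometry", {
  s <- make_subunit_model("gaussian_blob", 50, 5.36)
  expect_equal(max(s$data), 1)
  # FWHM within 10% of the nominal diameter, measured on the grid
  d <- dim(s$data)
  cc <- (d[1] + 1) / 2
  prof <- s$data[, cc, cc]
  ax <- (seq_along(prof) - cc) * 5.36
  fwhm <- diff(range(ax[prof >= 0.5])) + 5.36
  expect_lt(abs(fwhm - 50) / 50, 0.1)

  sh <- make_subunit_model("sphere_shell", 60, 4.51)
  dsh <- dim(sh$data)
  ctr <- sh$data[(dsh[1] + 1) / 2, (dsh[2] + 1) / 2, (dsh[3] + 1) / 2]
  expect_lt(ctr, 0.05)                       # hollow center
  expect_equal(max(sh$data), 1)              # maximal on the shell

  tl <- make_subunit_model("two_lobe", 45, 5.36)
  # polar: density is asymmetric along the intrinsic z axis
  flipped <- tl$data[, , dim(tl$data)[3]:1]
  expect_lt(vol_correlation(tl$data, flipped), 0.99)

  expect_error(make_subunit_model("gaussian_blob", 100, 5.36, box = 9),
               "diameter")
})

test_that("rendered filaments follow the helical lattice", {
  sub <- make_subunit_model("gaussian_blob", 18, 5.36)  # small: resolvable rise
  tr <- z_trace(64, 5.36)
  p <- helical_params(27.9, -167.7)
  rf <- render_filament(tr, p, sub, dim = rep(64, 3), voxel_size = 5.36,
                        two_strands = FALSE, helix_radius = 12)
  gt <- rf$ground_truth
  # subunit count: floor(L / rise) + 1 on a straight trace
  L <- (64 - 1) * 5.36
  expect_equal(nrow(gt), floor(L / 27.9) + 1)
  # azimuth of subunit k is k * twist (mod 360)
  expect_equal(gt$azimuth, (gt$subunit * -167.7) %% 360, tolerance = 1e-8)
  # axial autocorrelation of the z-density peaks at the rise +- one voxel
  ax <- apply(rf$volume$data, 3, sum)
  ac <- stats::acf(ax, lag.max = 12, plot = FALSE)$acf[, 1, 1]
  pk <- which(diff(sign(diff(ac))) == -2) + 1
  expect_true(length(pk) >= 1)
  expect_lt(abs(pk[1] * 5.36 - 27.9), 5.36 + 1e-9)
})

test_that("a trace shorter than one rise renders nothing, with a warning", {
  sub <- make_subunit_model("gaussian_blob", 18, 5.36)
  tiny <- filament_trace(cbind(c(50, 50), c(50, 50), c(50, 60)))
  expect_warning(
    rf <- render_filament(tiny, helical_params(27.9, -167.7), sub,
                          dim = rep(24, 3), voxel_size = 5.36),
    "shorter")
  expect_equal(nrow(rf$ground_truth), 0L)
})

test_that("subunit poses are recoverable from the noise-free rendering", {
  sub <- make_subunit_model("gaussian_blob", 24, 5.36)
  tr <- z_trace(48, 5.36)
  rf <- render_filament(tr, helical_params(55, 20), sub, dim = rep(48, 3),
                        voxel_size = 5.36, two_strands = FALSE,
                        helix_radius = 20)
  gt <- rf$ground_truth
  # template cross-correlation around one interior ground-truth pose peaks
  # at the recorded position within one voxel
  row <- gt[3, ]
  cc_at <- function(dx) {
    p <- c(row$x + dx, row$y, row$z) / 5.36
    win <- tomohelix:::resample_oriented(rf$volume, c(row$x + dx, row$y, row$z),
                                         diag(3), dim(sub$data)[1])
    vol_correlation(win$data, sub$data)
  }
  center <- cc_at(0)
  expect_gt(center, cc_at(8))
  expect_gt(center, cc_at(-8))
})

test_that("scatter_particles respects distances, seeds and edge cases", {
  mod <- make_subunit_model("gaussian_blob", 40, 5)
  blank <- scatter_particles(rep(48, 3), 5, 0, list(m = mod), seed = 1)
  expect_equal(nrow(blank$ground_truth), 0L)
  expect_equal(max(abs(blank$volume$data)), 0)

  a <- scatter_particles(rep(48, 3), 5, 10, list(m = mod),
                         min_distance = 45, seed = 7)
  b <- scatter_particles(rep(48, 3), 5, 10, list(m = mod),
                         min_distance = 45, seed = 7)
  expect_identical(a$ground_truth, b$ground_truth)
  ctr <- as.matrix(a$ground_truth[, c("center_x", "center_y", "center_z")])
  dmat <- as.matrix(stats::dist(ctr))
  expect_gte(min(dmat[upper.tri(dmat)]), 45)

  expect_error(scatter_particles(rep(24, 3), 5, 50, list(m = mod),
                                 min_distance = 60, seed = 1, max_tries = 50),
               "could not place")
})

test_that("the missing wedge removes the expected Fourier fraction", {
  frac <- missing_wedge_fraction(rep(64, 3), acquisition_geometry(-60, 60))
  expect_lt(abs(frac - 1 / 3), 0.02)
  # +/-90 degrees: nothing missing, identity operation
  set.seed(2)
  v <- new_volume(array(rnorm(32^3), rep(32, 3)), 1)
  v90 <- apply_missing_wedge(v, acquisition_geometry(-90, 90))
  expect_lt(max(abs(v90$data - v$data)) / max(abs(v$data)), 1e-10)
  # idempotence
  w1 <- apply_missing_wedge(v)
  w2 <- apply_missing_wedge(w1)
  expect_lt(max(abs(w1$data - w2$data)), 1e-10)
  # commutes with global density scaling
  s1 <- apply_missing_wedge(tomohelix:::with_data(v, 3.7 * v$data))
  expect_equal(s1$data, 3.7 * w1$data, tolerance = 1e-10)
})

test_that("additive noise hits the requested SNR and is seed-reproducible", {
  ph <- make_helical_reference(helical_params(27.9, -167.7), 64, 5.36)
  support <- abs(ph$data) > 0.05 * max(abs(ph$data))
  noisy <- add_noise(ph, snr = 1, seed = 11)
  meas <- stats::var(ph$data[support]) /
    stats::var((noisy$data - ph$data)[support])
  expect_lt(abs(meas - 1), 0.1)
  # high-SNR limit approaches the input
  clean <- add_noise(ph, snr = 1e8, seed = 11)
  expect_gt(vol_correlation(clean$data, ph$data), 0.99999)
  # seeds change the noise, never the signal
  n1 <- add_noise(ph, 1, seed = 1)
  n2 <- add_noise(ph, 1, seed = 2)
  expect_false(isTRUE(all.equal(n1$data, n2$data)))
  expect_identical(add_noise(ph, 1, seed = 1)$data, n1$data)
  expect_error(add_noise(new_volume(array(0, rep(8, 3)), 1), 1), "support")
})

test_that("dataset simulation is fully determined by its seed", {
  a <- simulate_filament_dataset(n_filaments = 2, snr = 0.5, seed = 3,
                                 tomo_dim = c(96, 96, 48),
                                 filament_length = 300)
  b <- simulate_filament_dataset(n_filaments = 2, snr = 0.5, seed = 3,
                                 tomo_dim = c(96, 96, 48),
                                 filament_length = 300)
  expect_identical(a$volumes[[1]]$data, b$volumes[[1]]$data)
  expect_identical(a$filament_info, b$filament_info)
})
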