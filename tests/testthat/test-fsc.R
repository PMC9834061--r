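test_that("identical half-maps give FSC 1 at every shell and Nyquist resolution", {
  ph <- make_helical_reference(helical_params(27.9, -167.7), 48, 5.36)
  f <- compute_fsc(ph, ph)
  expect_true(all(f$fsc > 0.9999))
  expect_equal(f$resolution, 2 * 5.36, tolerance = 1e-9)
})

test_that("FSC against independent noise fluctuates near zero", {
  set.seed(12)
  ph <- make_helical_reference(helical_params(27.9, -167.7), 48, 5.36)
  nz <- new_volume(array(rnorm(48^3), rep(48, 3)), 5.36)
  f <- compute_fsc(ph, nz)
  expect_lt(mean(abs(f$fsc[5:length(f$fsc)])), 0.05)
})

test_that("grid mismatch is rejected", {
  a <- new_volume(array(0, rep(16, 3)), 2); a$data[1] <- 1
  b <- new_volume(array(0, rep(24, 3)), 2); b$data[1] <- 1
  expect_error(compute_fsc(a, b), "grid")
})

test_that("per-shell FSC follows SNR/(SNR+1) for a known phantom", {
  set.seed(9)
  ph <- make_helical_reference(helical_params(27.9, -167.7), 48, 5.36)
  sig <- ph$data
  support <- abs(sig) > 0.05 * max(abs(sig))
  nsd <- sqrt(stats::var(as.vector(sig[support])))   # SNR 1
  a <- tomohelix:::with_data(ph, sig + array(rnorm(length(sig), 0, nsd),
                                             dim(sig)))
  b <- tomohelix:::with_data(ph, sig + array(rnorm(length(sig), 0, nsd),
                                             dim(sig)))
  f <- compute_fsc(a, b)
  sh <- tomohelix:::fourier_shells(dim(sig), 5.36)
  ok <- !is.na(sh)
  ps <- as.numeric(rowsum(Mod(stats::fft(sig)[ok])^2,
                          as.integer(sh[ok]) + 1L))
  nz <- array(rnorm(length(sig), 0, nsd), dim(sig))
  pn <- as.numeric(rowsum(Mod(stats::fft(nz)[ok])^2,
                          as.integer(sh[ok]) + 1L))
  pred <- (ps / pn) / (ps / pn + 1)
  expect_lt(mean(abs(f$fsc - pred)), 0.05)
  expect_lt(max(abs(f$fsc - pred)), 0.15)
})

test_that("polarity votes count correctly and can be applied", {
  tab <- data.frame(filament_id = rep(1, 10),
                    polarity_flag = rep("up", 10))
  v <- vote_polarity(tab)
  expect_equal(v$votes$polarity, "up")
  expect_equal(v$votes$confidence, 1)

  tab2 <- data.frame(filament_id = rep(2, 10),
                     polarity_flag = c(rep("up", 6), rep("down", 4)))
  v2 <- vote_polarity(tab2)
  expect_equal(v2$votes$polarity, "up")
  expect_equal(v2$votes$confidence, 0.6)

  single <- data.frame(filament_id = 3, polarity_flag = "down")
  v3 <- vote_polarity(single)
  expect_true(v3$votes$singleton)
  expect_equal(v3$votes$confidence, 1)

  # diagnostic by default: the table is untouched
  tab3 <- data.frame(filament_id = rep(1, 4), psi = c(2, -3, 181, 1),
                     rot = c(10, 20, 30, 40),
                     shift_axial = c(1, 2, 3, 4))
  tab3$polarity_flag <- ifelse(cos(tab3$psi * pi / 180) >= 0, "up", "down")
  v4 <- vote_polarity(tab3)
  expect_identical(v4$table$psi, tab3$psi)
  # apply = TRUE flips only the minority segment
  v5 <- vote_polarity(tab3, apply = TRUE)
  expect_equal(v5$table$psi[3], (181 + 180) %% 360)
  expect_equal(v5$table$rot[3], (-30) %% 360)
  expect_equal(v5$table$shift_axial[3], -3)
  expect_identical(v5$table$psi[-3], tab3$psi[-3])
})
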