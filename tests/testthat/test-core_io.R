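test_that("MRC volumes round-trip losslessly", {
  set.seed(1)
  v <- new_volume(array(rnorm(16^3), rep(16, 3)), 5.36, origin = c(1, 2, 3))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(dim(v2$data), dim(v$data))
  expect_equal(v2$voxel_size, 5.36, tolerance = 1e-6)
  expect_equal(v2$origin, c(1, 2, 3), tolerance = 1e-5)
  # float32 storage: round-trip exact to single precision
  expect_lt(max(abs(v2$data - v$data)), 1e-6 * max(abs(v$data)))

  # a single hot voxel survives untouched
  w <- new_volume(array(0, rep(8, 3)), 4.51)
  w$data[2, 3, 4] <- 1
  write_volume(w, f)
  w2 <- read_volume(f)
  expect_identical(which(w2$data == 1), which(w$data == 1))
  expect_equal(sum(w2$data != 0), 1L)
})

test_that("MRC header records physical cell dimensions", {
  v <- new_volume(array(0, rep(64, 3)), 5.36)
  v$data[1] <- 1
  f <- withr::local_tempfile(fileext = ".mrc")
  write_volume(v, f)
  read_cella <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, 10 * 4)
    readBin(con, "numeric", 3, size = 4, endian = "little")
  }
  expect_equal(read_cella(f)[1], 64 * 5.36, tolerance = 1e-3)   # 343.04 A

  v2 <- new_volume(array(seq_len(32^3) * 1e-4, rep(32, 3)), 4.51)
  write_volume(v2, f)
  expect_equal(read_cella(f)[1], 144.32, tolerance = 1e-3)
})

test_that("malformed MRC files raise format errors, not partial volumes", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(100), f)                      # truncated header
  expect_error(read_volume(f), "truncated")
  v <- new_volume(array(rnorm(8^3), rep(8, 3)), 2)
  write_volume(v, f)
  # truncate the data section
  raw_all <- readBin(f, "raw", file.info(f)$size)
  writeBin(raw_all[1:1200], f)
  expect_error(read_volume(f), "truncated")
  expect_error(write_volume(new_volume(array(1, c(1, 1, 1))[0, , , drop = FALSE],
                                       1), f))
})

test_that("particle tables round-trip through STAR and TSV", {
  df <- data.frame(particle_id = c("p1", "p2", "p3"),
                   center_x = c(10.123456789, -3, 0.5),
                   center_y = c(0, 1, 2), center_z = c(5, 6, 7),
                   euler_phi = c(0, 90.5, -170),
                   euler_theta = c(10, 20, 30),
                   euler_psi = c(0, 0, 1),
                   custom_note = c("a", "b", "c"),   # unknown column
                   stringsAsFactors = FALSE)
  for (ext in c(".star", ".tsv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_particle_table(df, f)
    back <- read_particle_table(f)
    expect_equal(back$center_x, df$center_x, tolerance = 1e-12)
    expect_identical(back$custom_note, df$custom_note)
    expect_identical(names(back), names(df))
  }
})

test_that("schema violations are reported by column name", {
  df <- data.frame(particle_id = 1:2, center_x = 0, center_y = 0,
                   center_z = 0)
  expect_error(validate_particle_table(df), "euler_phi")
  f <- withr::local_tempfile(fileext = ".star")
  good <- data.frame(particle_id = 1, center_x = 0, center_y = 0,
                     center_z = 0, euler_phi = 0, euler_theta = 0,
                     euler_psi = 0)
  dup <- rbind(good, good)
  expect_error(validate_particle_table(dup), "unique")
})

test_that("an empty table round-trips without error", {
  f <- withr::local_tempfile(fileext = ".star")
  empty <- data.frame(particle_id = character(0), center_x = numeric(0),
                      center_y = numeric(0), center_z = numeric(0),
                      euler_phi = numeric(0), euler_theta = numeric(0),
                      euler_psi = numeric(0))
  write_particle_table(empty, f)
  back <- read_particle_table(f)
  expect_equal(nrow(back), 0L)
  expect_identical(names(back), names(empty))
})

test_that("run configuration validates physical consistency", {
  cfg <- run_config()
  expect_equal(config_voxel_size(cfg), 4.51 * 4)
  expect_error(run_config(tilt_min = 60, tilt_max = -60), "tilt_min")
  expect_error(run_config(lowpass_reference = 5), "twice")
  expect_error(run_config(n_iterations = 0), "n_iterations")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  cfg2 <- read_run_config(f)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("run events are recorded and serializable", {
  reset_run_record()
  log_run_event("unit_test", seed = 42L, n = 3)
  rec <- get_run_record()
  expect_equal(rec[[length(rec)]]$params$seed, 42L)
  f <- withr::local_tempfile(fileext = ".json")
  write_run_record(f)
  back <- jsonlite::read_json(f)
  expect_equal(back[[length(back)]]$stage, "unit_test")
  reset_run_record()
})
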