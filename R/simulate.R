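#' Single-axis acquisition geometry
#'
#' Tilt range and axis of the simulated single-axis tomographic
#' acquisition; defines the missing wedge. Defaults follow the study
#' acquisition: -60 to +60 degrees in 2 degree increments, tilt axis = y.
#'
#' @param tilt_min,tilt_max tilt range in degrees, `tilt_min < 0 < tilt_max`,
#'   both within \[-90, 90\].
#' @param increment tilt increment in degrees.
#' @param tilt_axis unit vector in the xy plane (length-2).
#' @return an `acquisition_geometry` object.
#' @export
acquisition_geometry <- function(tilt_min = -60, tilt_max = 60,
                                 increment = 2, tilt_axis = c(0, 1)) {
  if (!(tilt_min < 0 && 0 < tilt_max)) stop("need tilt_min < 0 < tilt_max")
  if (abs(tilt_min) > 90 || abs(tilt_max) > 90) stop("|tilt| must be <= 90")
  if (length(tilt_axis) != 2L || sum(tilt_axis^2) == 0)
    stop("tilt_axis must be a non-zero length-2 vector in the xy plane")
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max,
                 increment = increment,
                 tilt_axis = tilt_axis / sqrt(sum(tilt_axis^2))),
            class = "acquisition_geometry")
}

# Binary sampling mask of the single-axis tilt geometry on a Fourier grid.
# A Fourier voxel is sampled iff some tilt plane in the range passes
# through it; the unsampled complement is the missing wedge.
wedge_sampling_mask <- function(dm, geometry) {
  kx <- fft_freqs(dm[1], 1)
  ky <- fft_freqs(dm[2], 1)
  kz <- fft_freqs(dm[3], 1)
  a <- geometry$tilt_axis
  p <- c(a[2], -a[1])                  # in-plane direction perpendicular to axis
  kp <- outer(kx * p[1], ky * p[2], `+`)          # nx x ny
  kp3 <- array(rep(kp, dm[3]), dim = dm)
  kz3 <- array(rep(kz, each = dm[1] * dm[2]), dim = dm)
  th <- atan2(-kz3, kp3) * 180 / pi
  th[th > 90] <- th[th > 90] - 180
  th[th <= -90] <- th[th <= -90] + 180
  eps <- 1e-9
  (th >= geometry$tilt_min - eps & th <= geometry$tilt_max + eps) |
    (kp3 == 0 & kz3 == 0)
}

#' Fraction of resolvable Fourier space lost to the missing wedge
#'
#' Counts unsampled Fourier voxels within the Nyquist disc of the plane
#' perpendicular to the tilt axis (the region where "fraction of Fourier
#' space" is geometrically meaningful; the corners of the rectangular grid
#' lie beyond Nyquist). For a symmetric +/-60 degree range this is 1/3 —
#' a wedge of half-angle 30 degrees on both sides of the beam axis.
#'
#' @param dm length-3 grid dimensions.
#' @param geometry an [acquisition_geometry()].
#' @return scalar fraction in \[0, 1\].
#' @export
missing_wedge_fraction <- function(dm, geometry = acquisition_geometry()) {
  m <- wedge_sampling_mask(dm, geometry)
  a <- geometry$tilt_axis
  p <- c(a[2], -a[1])
  kx <- fft_freqs(dm[1], 1)
  ky <- fft_freqs(dm[2], 1)
  kz <- fft_freqs(dm[3], 1)
  kp <- outer(kx * p[1], ky * p[2], `+`)
  kp3 <- array(rep(kp, dm[3]), dim = dm)
  kz3 <- array(rep(kz, each = dm[1] * dm[2]), dim = dm)
  disc <- kp3^2 + kz3^2 <= 0.25 + 1e-12
  mean(!m[disc])
}

#' Apply the missing wedge of a limited tilt range
#'
#' Zeroes the Fourier coefficients of a volume that fall outside the
#' region sampled by a single-axis tilt series with the given geometry;
#' the output is real-valued. A +/-90 degree range is the identity, and
#' the operation is idempotent.
#'
#' @param volume a `tomo_volume`.
#' @param geometry an [acquisition_geometry()].
#' @return wedge-filtered `tomo_volume`.
#' @export
apply_missing_wedge <- function(volume, geometry = acquisition_geometry()) {
  stopifnot_volume(volume)
  m <- wedge_sampling_mask(dim(volume$data), geometry)
  f <- stats::fft(volume$data)
  f[!m] <- 0
  with_data(volume, Re(stats::fft(f, inverse = TRUE)) / length(f))
}

#' Additive Gaussian noise at a configured SNR
#'
#' SNR is defined as signal variance over noise variance measured within
#' the signal support mask (by default, voxels whose |density| exceeds 5%
#' of the maximum). Zero-mean white Gaussian noise of the implied standard
#' deviation is added to every voxel; the result is reproducible under a
#' fixed seed.
#'
#' @param volume a `tomo_volume` holding the noise-free signal.
#' @param snr target signal-to-noise variance ratio (> 0).
#' @param seed integer RNG seed.
#' @param support optional logical array marking the signal support.
#' @return noisy `tomo_volume` with attribute `"noise_sd"`.
#' @export
add_noise <- function(volume, snr, seed = 1L, support = NULL) {
  stopifnot_volume(volume)
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive")
  if (is.null(support))
    support <- abs(volume$data) > 0.05 * max(abs(volume$data))
  if (!any(support)) stop("empty signal support: SNR is undefined")
  sig_var <- stats::var(as.vector(volume$data[support]))
  if (sig_var == 0) stop("signal has zero variance on its support: SNR undefined")
  sd_noise <- sqrt(sig_var / snr)
  set.seed(seed)
  noisy <- volume$data + array(stats::rnorm(length(volume$data), 0, sd_noise),
                               dim(volume$data))
  out <- with_data(volume, noisy)
  attr(out, "noise_sd") <- sd_noise
  out
}

#' Render a helical filament along a trace
#'
#' Places copies of a subunit density every `rise` Angstrom of arc length
#' along the interpolated centerline, advancing the azimuth about the local
#' axis by `twist` degrees per subunit; with `two_strands`, a second strand
#' is added at a 180 degree azimuthal offset (same z positions), producing
#' the twisted double-stranded appearance of actin-family filaments.
#' Subunit centers sit `helix_radius` Angstrom off the axis and each copy
#' is rotated with the local frame (its intrinsic z tilted from the
#' tangent toward the radial direction by `lobe_tilt`, so that asymmetric
#' subunits make the filament polar). Every placed subunit is listed in the
#' returned ground truth.
#'
#' @param trace a [filament_trace()].
#' @param params a [helical_params()].
#' @param subunit a subunit `tomo_volume` from [make_subunit_model()].
#' @param dim length-3 grid size of the output volume (voxels).
#' @param voxel_size voxel size in Angstrom.
#' @param origin physical origin of the output grid.
#' @param two_strands add the 180-degree offset second strand (default TRUE).
#' @param helix_radius distance of subunit centers from the axis (Angstrom).
#' @param lobe_tilt tilt of the subunit intrinsic axis away from the local
#'   tangent, degrees.
#' @param phase0 azimuth of subunit 0 in degrees.
#' @return list with `volume` (the rendered `tomo_volume`) and
#'   `ground_truth` (one row per placed subunit: positions in Angstrom,
#'   azimuth, strand, arc position and ZYZ Euler angles of the placement).
#' @export
render_filament <- function(trace, params, subunit, dim, voxel_size,
                            origin = c(0, 0, 0), two_strands = TRUE,
                            helix_radius = 15, lobe_tilt = 40, phase0 = 0) {
  stopifnot(inherits(trace, "filament_trace"), inherits(params, "helical_params"))
  stopifnot_volume(subunit)
  fr <- trace_frames(trace)
  if (fr$length < params$rise) {
    warning("trace shorter than one rise: no subunits rendered")
    gt <- data.frame(filament_id = integer(0), subunit = integer(0),
                     strand = integer(0), s = numeric(0),
                     azimuth = numeric(0), x = numeric(0), y = numeric(0),
                     z = numeric(0), euler_phi = numeric(0),
                     euler_theta = numeric(0), euler_psi = numeric(0))
    vol <- new_volume(array(0, dim), voxel_size, origin)
    return(list(volume = vol, ground_truth = gt))
  }
  nk <- floor(fr$length / params$rise)
  s_k <- (0:nk) * params$rise
  f <- frames_at(fr, s_k)
  strands <- if (two_strands) c(0, 180) else 0

  rows <- list()
  n_total <- (nk + 1) * length(strands)
  pos <- matrix(0, n_total, 3)
  rots <- array(0, c(3, 3, n_total))
  m <- 0
  for (st in seq_along(strands)) {
    for (k in 0:nk) {
      m <- m + 1
      i <- k + 1
      phi <- phase0 + k * params$twist + strands[st]
      phir <- deg2rad(phi)
      radial <- cos(phir) * f$N1[i, ] + sin(phir) * f$N2[i, ]
      tang <- f$T[i, ]
      third <- c(tang[2] * radial[3] - tang[3] * radial[2],
                 tang[3] * radial[1] - tang[1] * radial[3],
                 tang[1] * radial[2] - tang[2] * radial[1])
      B <- cbind(radial, third, tang)
      R <- B %*% rot_y(lobe_tilt)
      ctr <- f$P[i, ] + helix_radius * radial
      pos[m, ] <- ctr
      rots[, , m] <- R
      eul <- matrix_to_euler(R)
      rows[[m]] <- data.frame(filament_id = trace$filament_id, subunit = k,
                              strand = st, s = s_k[i],
                              azimuth = ((phi %% 360) + 360) %% 360,
                              x = ctr[1], y = ctr[2], z = ctr[3],
                              euler_phi = eul[1], euler_theta = eul[2],
                              euler_psi = eul[3])
    }
  }
  gt <- do.call(rbind, rows)
  pos_vox <- sweep(pos, 2, origin) / voxel_size
  data <- cpp_render_subunits(as.integer(dim), subunit$data, pos_vox,
                              as.numeric(rots))
  list(volume = new_volume(data, voxel_size, origin), ground_truth = gt)
}

#' Scatter globular particles into a field
#'
#' Places `n` particles with uniformly random orientations and
#' non-overlapping centers (minimum pairwise distance `min_distance`,
#' bounded rejection sampling) into a blank volume. Species labels cycle
#' deterministically through `names(species_models)` so that multi-species
#' fields are balanced.
#'
#' @param dim length-3 grid size in voxels.
#' @param voxel_size voxel size in Angstrom.
#' @param n number of particles (>= 0).
#' @param species_models named list of subunit `tomo_volume` densities.
#' @param min_distance minimum center-to-center distance in Angstrom.
#' @param seed integer RNG seed.
#' @param margin keep centers this far (Angstrom) from the volume faces;
#'   defaults to half the largest species box.
#' @param max_tries placement attempts per particle before giving up.
#' @return list with `volume` and `ground_truth` (a particle table with a
#'   `label` column).
#' @export
scatter_particles <- function(dim, voxel_size, n, species_models,
                              min_distance = 0, seed = 1L, margin = NULL,
                              max_tries = 2000L) {
  if (n < 0) stop("n must be >= 0")
  if (is.null(names(species_models)) && length(species_models))
    names(species_models) <- paste0("species", seq_along(species_models))
  ext <- if (length(species_models))
    max(vapply(species_models, function(s) max(dim(s$data)) * s$voxel_size,
               numeric(1))) else 0
  if (is.null(margin)) margin <- ext / 2
  lo <- rep(margin, 3)
  hi <- dim * voxel_size - margin
  if (n > 0 && any(hi <= lo))
    stop("volume too small for the requested margin")
  set.seed(seed)
  centers <- matrix(0, 0, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- stats::runif(3, lo, hi)
      if (!nrow(centers) ||
          min(sqrt(colSums((t(centers) - p)^2))) >= min_distance) {
        centers <- rbind(centers, p)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place %d particles at min_distance %.1f A; placed %d",
                   n, min_distance, nrow(centers)))
  }
  labels <- if (n > 0) rep(names(species_models), length.out = n) else character(0)
  rots <- array(0, c(3, 3, max(n, 1)))
  eul <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    R <- quat_to_matrix(q)
    rots[, , i] <- R
    eul[i, ] <- matrix_to_euler(R)
  }
  data <- array(0, dim)
  for (sp in unique(labels)) {
    idx <- which(labels == sp)
    sub <- species_models[[sp]]
    pos_vox <- centers[idx, , drop = FALSE] / voxel_size
    data <- data + cpp_render_subunits(as.integer(dim), sub$data, pos_vox,
                                       as.numeric(rots[, , idx, drop = FALSE]))
  }
  gt <- data.frame(particle_id = seq_len(n),
                   label = labels,
                   center_x = if (n) centers[, 1] else numeric(0),
                   center_y = if (n) centers[, 2] else numeric(0),
                   center_z = if (n) centers[, 3] else numeric(0),
                   euler_phi = if (n) eul[, 1] else numeric(0),
                   euler_theta = if (n) eul[, 2] else numeric(0),
                   euler_psi = if (n) eul[, 3] else numeric(0))
  list(volume = new_volume(data, voxel_size), ground_truth = gt)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Simulate a filament dataset with exact ground truth
#'
#' The stand-in for the study's tomograms: each filament is rendered into
#' its own tomogram-like volume with F-actin-like helical geometry, the
#' single-axis missing wedge is applied, and Gaussian noise is added at the
#' configured SNR. Filaments lie in the xy plane (as in real tomograms) at
#' random in-plane directions, with random azimuthal phase, a gentle random
#' curvature, and random polarity (half the traces run opposite to the
#' helix growth direction, modelling arbitrary picking direction).
#'
#' @param n_filaments number of filaments.
#' @param params generative [helical_params()]; defaults to the refined
#'   filament values (rise 27.9 A, twist -167.7 deg).
#' @param snr signal-to-noise variance ratio of the tomograms.
#' @param geometry [acquisition_geometry()] for the missing wedge.
#' @param voxel_size working voxel size in Angstrom (default 5.36 A,
#'   i.e. 2.68 A pixels at binning 2).
#' @param tomo_dim per-filament volume size in voxels.
#' @param filament_length filament length in Angstrom.
#' @param subunit_kind,subunit_diameter subunit model (see
#'   [make_subunit_model()]); the ~70 A filament diameter that results is a
#'   modelling default, no measured value being available.
#' @param helix_radius subunit center offset from the axis in Angstrom.
#' @param two_strands render the 180-degree offset second strand.
#' @param curvature_amp amplitude (Angstrom) of the random in-plane bowing
#'   of each trace.
#' @param seed integer seed; all randomness derives from it.
#' @return list with `volumes` (list of noisy `tomo_volume`s), `traces`
#'   (list of [filament_trace()]s, reversed for polarity-flipped
#'   filaments), `filament_info` (per-filament ground truth: direction,
#'   phase, polarity), and `subunit_truth` (per-subunit poses).
#' @export
simulate_filament_dataset <- function(n_filaments = 20,
                                      params = helical_params(27.9, -167.7),
                                      snr = 0.1,
                                      geometry = acquisition_geometry(),
                                      voxel_size = 5.36,
                                      tomo_dim = c(160, 160, 64),
                                      filament_length = 780,
                                      subunit_kind = "two_lobe",
                                      subunit_diameter = 45,
                                      helix_radius = 15,
                                      two_strands = TRUE,
                                      curvature_amp = 8,
                                      seed = 1L) {
  set.seed(seed)
  sub <- make_subunit_model(subunit_kind, subunit_diameter, voxel_size)
  center <- tomo_dim * voxel_size / 2
  volumes <- list()
  traces <- list()
  info <- list()
  truth <- list()
  draws <- data.frame(theta = stats::runif(n_filaments, 0, 360),
                      phase = stats::runif(n_filaments, 0, 360),
                      bow = stats::runif(n_filaments, -1, 1) * curvature_amp,
                      flip = stats::runif(n_filaments) < 0.5,
                      nseed = sample.int(.Machine$integer.max %/% 2, n_filaments))
  for (i in seq_len(n_filaments)) {
    th <- deg2rad(draws$theta[i])
    dvec <- c(cos(th), sin(th), 0)
    perp <- c(-sin(th), cos(th), 0)
    ss <- seq(-filament_length / 2, filament_length / 2, length.out = 7)
    bow <- draws$bow[i] * (1 - (2 * ss / filament_length)^2)  # parabolic sag
    pts <- t(vapply(seq_along(ss),
                    function(j) center + ss[j] * dvec + bow[j] * perp,
                    numeric(3)))
    tr <- filament_trace(pts, filament_id = i, source_volume_id = i)
    rf <- render_filament(tr, params, sub, dim = tomo_dim,
                          voxel_size = voxel_size, two_strands = two_strands,
                          helix_radius = helix_radius,
                          phase0 = draws$phase[i])
    vol <- apply_missing_wedge(rf$volume, geometry)
    support <- rf$volume$data > 0.05 * max(rf$volume$data)
    vol <- add_noise(vol, snr, seed = draws$nseed[i], support = support)
    # polarity: half of the traces are recorded "backwards"
    trace_out <- if (draws$flip[i]) reverse_trace(tr) else tr
    volumes[[i]] <- vol
    traces[[i]] <- trace_out
    info[[i]] <- data.frame(filament_id = i, direction_deg = draws$theta[i],
                            phase0 = draws$phase[i],
                            polarity_up = !draws$flip[i])
    truth[[i]] <- rf$ground_truth
  }
  log_run_event("simulate_filament_dataset", n_filaments = n_filaments,
                rise = params$rise, twist = params$twist, snr = snr,
                voxel_size = voxel_size, seed = seed)
  list(volumes = volumes, traces = traces,
       filament_info = do.call(rbind, info),
       subunit_truth = do.call(rbind, truth),
       params = params, voxel_size = voxel_size, subunit = sub)
}
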