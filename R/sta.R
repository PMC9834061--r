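#' Sub-tomogram alignment by constrained cross-correlation
#'
#' Hierarchical angular search: a coarse global grid of ZYZ Euler triplets
#' (quasi-uniform: theta rings with phi counts scaled by sin(theta)),
#' followed by a local refinement pass at a finer step around the best
#' orientation. For every candidate orientation the reference is rotated
#' and the translation found by 3D FFT cross-correlation; when an
#' [acquisition_geometry()] is supplied, both volumes are restricted to
#' the particle's sampled Fourier region (wedge-masked, "constrained"
#' correlation), so the missing wedge cannot bias the scores.
#'
#' @param particles list of `tomo_volume`s (equal grids).
#' @param reference reference `tomo_volume`; low-pass filter it to the
#'   desired cutoff (e.g. 60 A) before calling.
#' @param geometry optional [acquisition_geometry()] of the particles.
#' @param angle_step coarse angular step in degrees.
#' @param local_refine number of refinement levels (each halves the step).
#' @param max_shift translation cap in Angstrom.
#' @return particle table with `euler_phi/theta/psi` (rotation of the
#'   reference into the particle), `shift_x/y/z` (Angstrom) and `score`
#'   (wedge-masked normalized correlation).
#' @export
align_subtomograms <- function(particles, reference, geometry = NULL,
                               angle_step = 30, local_refine = 2,
                               max_shift = 20) {
  if (!length(particles))
    return(data.frame(particle_id = integer(0), euler_phi = numeric(0),
                      euler_theta = numeric(0), euler_psi = numeric(0),
                      shift_x = numeric(0), shift_y = numeric(0),
                      shift_z = numeric(0), score = numeric(0)))
  stopifnot_volume(reference)
  d <- dim(particles[[1]]$data)
  vx <- particles[[1]]$voxel_size
  wmask <- if (is.null(geometry)) NULL else wedge_sampling_mask(d, geometry)
  rows <- vector("list", length(particles))
  grid0 <- euler_grid(angle_step)
  for (i in seq_along(particles)) {
    part <- particles[[i]]
    fp <- stats::fft(part$data - mean(part$data))
    if (!is.null(wmask)) fp[!wmask] <- 0
    best <- score_orientations(fp, reference, grid0, wmask, max_shift, vx)
    step <- angle_step
    for (lv in seq_len(local_refine)) {
      step <- step / 2
      g <- local_euler_grid(best$euler, step)
      cand <- score_orientations(fp, reference, g, wmask, max_shift, vx)
      if (cand$score > best$score) best <- cand
    }
    rows[[i]] <- data.frame(particle_id = i,
                            euler_phi = best$euler[1],
                            euler_theta = best$euler[2],
                            euler_psi = best$euler[3],
                            shift_x = best$shift[1], shift_y = best$shift[2],
                            shift_z = best$shift[3], score = best$score)
  }
  do.call(rbind, rows)
}

# quasi-uniform ZYZ grid at a given step (degrees)
euler_grid <- function(step) {
  thetas <- seq(0, 180, by = step)
  out <- list()
  for (th in thetas) {
    nphi <- max(1L, round(360 * sin(deg2rad(th)) / step))
    phis <- seq(0, 360, length.out = nphi + 1L)[-(nphi + 1L)]
    psis <- seq(0, 360 - step, by = step)
    out[[length(out) + 1L]] <- expand.grid(phi = phis, theta = th, psi = psis)
  }
  as.matrix(do.call(rbind, out))
}

local_euler_grid <- function(center, step) {
  g <- expand.grid(dphi = c(-step, 0, step), dtheta = c(-step, 0, step),
                   dpsi = c(-step, 0, step))
  cbind(phi = center[1] + g$dphi, theta = pmin(pmax(center[2] + g$dtheta, 0), 180),
        psi = center[3] + g$dpsi)
}

score_orientations <- function(fp, reference, grid, wmask, max_shift, vx) {
  d <- dim(reference$data)
  np <- sqrt(sum(Mod(fp)^2))
  best <- list(score = -Inf)
  n <- prod(d)
  sx <- ((0:(d[1] - 1) + d[1] %/% 2) %% d[1]) - d[1] %/% 2
  sy <- ((0:(d[2] - 1) + d[2] %/% 2) %% d[2]) - d[2] %/% 2
  sz <- ((0:(d[3] - 1) + d[3] %/% 2) %% d[3]) - d[3] %/% 2
  cap <- floor(max_shift / vx)
  okx <- abs(sx) <= cap; oky <- abs(sy) <= cap; okz <- abs(sz) <= cap
  ok <- outer(outer(okx, oky, `&`), okz, `&`)
  for (r in seq_len(nrow(grid))) {
    R <- euler_to_matrix(grid[r, 1], grid[r, 2], grid[r, 3])
    rot <- rotate_volume(reference, R)
    fr <- stats::fft(rot$data - mean(rot$data))
    if (!is.null(wmask)) fr[!wmask] <- 0
    nr <- sqrt(sum(Mod(fr)^2))
    if (nr == 0) next
    cc <- Re(stats::fft(fp * Conj(fr), inverse = TRUE)) / n
    cc[!ok] <- -Inf
    w <- which.max(cc)
    idx <- arrayInd(w, d)
    sc <- cc[w] * n / (np * nr)
    if (sc > best$score)
      best <- list(score = sc, euler = as.numeric(grid[r, ]),
                   shift = c(sx[idx[1]], sy[idx[2]], sz[idx[3]]) * vx)
  }
  best
}

# pose a particle back into the reference frame given its alignment row
align_particle_to_ref <- function(particle, euler, shift) {
  R <- euler_to_matrix(euler[1], euler[2], euler[3])
  rotate_volume(particle, t(R), shift = as.numeric(-t(R) %*% shift))
}

#' Average aligned sub-tomograms with wedge-coverage weighting
#'
#' Rotates and shifts every particle into the reference frame and averages
#' them in Fourier space, normalizing each Fourier voxel by its wedge
#' coverage (the sum of the rotated per-particle sampling masks, floored
#' at a small constant so uncovered voxels stay zero instead of blowing
#' up).
#'
#' @param particles list of `tomo_volume`s.
#' @param table alignment table from [align_subtomograms()] (or ground
#'   truth): columns `euler_phi/theta/psi`, optional `shift_x/y/z`.
#' @param geometry optional [acquisition_geometry()]; without it a plain
#'   real-space average is returned.
#' @return the average `tomo_volume`.
#' @export
average_subtomograms <- function(particles, table, geometry = NULL) {
  if (!length(particles)) stop("zero particles: nothing to average")
  if (length(particles) != nrow(table))
    stop("one table row per particle required")
  d <- dim(particles[[1]]$data)
  shifts <- cbind(table$shift_x %||% 0, table$shift_y %||% 0,
                  table$shift_z %||% 0)
  if (is.null(geometry)) {
    acc <- array(0, d)
    for (i in seq_along(particles)) {
      al <- align_particle_to_ref(particles[[i]],
                                  c(table$euler_phi[i], table$euler_theta[i],
                                    table$euler_psi[i]), shifts[i, ])
      acc <- acc + al$data
    }
    return(new_volume(acc / length(particles), particles[[1]]$voxel_size))
  }
  wmask <- wedge_sampling_mask(d, geometry)
  # rotate the sampling mask in a centered layout, then shift back
  wvol <- new_volume(fftshift3(array(as.numeric(wmask), d)),
                     particles[[1]]$voxel_size)
  facc <- array(0 + 0i, d)
  cacc <- array(0, d)
  for (i in seq_along(particles)) {
    eul <- c(table$euler_phi[i], table$euler_theta[i], table$euler_psi[i])
    al <- align_particle_to_ref(particles[[i]], eul, shifts[i, ])
    R <- euler_to_matrix(eul[1], eul[2], eul[3])
    # the particle's sampled region, carried through the inverse rotation
    wrot <- rotate_volume(wvol, t(R))
    wr <- fftshift3(wrot$data) >= 0.5
    facc <- facc + stats::fft(al$data) * wr
    cacc <- cacc + wr
  }
  avg <- Re(stats::fft(facc / pmax(cacc, 0.5), inverse = TRUE)) / prod(d)
  new_volume(avg, particles[[1]]$voxel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# move the zero-frequency voxel between corner and center layouts;
# self-inverse for even dimensions
fftshift3 <- function(x) {
  d <- dim(x)
  ix <- lapply(d, function(n) ((0:(n - 1) + n %/% 2) %% n) + 1)
  x[ix[[1]], ix[[2]], ix[[3]]]
}

#' Reference-based classification of sub-tomograms
#'
#' Classifies aligned sub-tomograms (alignments held fixed; use
#' [align_subtomograms()] first if unknown). With seed `references`, each
#' particle is assigned to the best-correlating reference (band-limited,
#' wedge-constrained) and the assignment polished by
#' expectation-maximization. Without references the method is focused
#' difference classification: per-particle residuals against the
#' wedge-weighted global mean are computed inside the particle's sampled
#' Fourier region and band limit, the cross-particle variance map
#' pinpoints where the population genuinely differs (e.g. a variable
#' surface density), and particles are clustered on their residual
#' density inside that focus region, followed by focused EM refinement
#' with leave-one-out class means. Restricting the comparison to the
#' focus region is what keeps the differently oriented missing wedges of
#' the shared bulk from masquerading as class structure.
#'
#' @param particles list of `tomo_volume`s.
#' @param table alignment table (one row per particle).
#' @param k number of classes.
#' @param references optional list of k seed `tomo_volume`s.
#' @param geometry optional [acquisition_geometry()] for wedge-aware
#'   residuals and averaging.
#' @param n_iter maximum EM iterations.
#' @param seed RNG seed for the k-means seeding.
#' @param mask_radius soft spherical comparison mask radius (Angstrom);
#'   default half the box.
#' @param lowpass resolution band (Angstrom) for the residuals (default
#'   18): classification differences of interest are large-scale, and the
#'   band limit suppresses orientation-dependent interpolation artifacts.
#' @param focus_quantile variance-map quantile defining the focus region
#'   (default 0.995).
#' @return list with `assignments`, `averages` (list of `tomo_volume`),
#'   `population`, `scores` (n x k matrix), `focus` (logical array, or
#'   NULL in reference mode).
#' @export
classify_subtomograms <- function(particles, table, k, references = NULL,
                                  geometry = NULL, n_iter = 10, seed = 1L,
                                  mask_radius = NULL, lowpass = 18,
                                  focus_quantile = 0.995) {
  n <- length(particles)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop(sprintf("k (%d) exceeds the number of particles (%d)", k, n))
  d <- dim(particles[[1]]$data)
  vx <- particles[[1]]$voxel_size
  if (is.null(mask_radius)) mask_radius <- d[1] * vx / 2 - 2 * vx
  msk <- sphere_mask(d, vx, mask_radius)
  band <- kradius3(d, vx) <= 1 / lowpass
  wvol <- NULL
  if (!is.null(geometry)) {
    wmask <- wedge_sampling_mask(d, geometry)
    wvol <- new_volume(fftshift3(array(as.numeric(wmask), d)), vx)
  }
  shifts <- cbind(table$shift_x %||% 0, table$shift_y %||% 0,
                  table$shift_z %||% 0)
  gmean <- average_subtomograms(particles, table, geometry)$data
  Fg <- stats::fft(gmean)
  Fg[!band] <- 0
  # band-limited, wedge-restricted real-space residuals per particle
  res <- array(0, c(prod(d), n))
  for (i in seq_len(n)) {
    eul <- c(table$euler_phi[i], table$euler_theta[i], table$euler_psi[i])
    al <- align_particle_to_ref(particles[[i]], eul, shifts[i, ])
    Fi <- stats::fft(al$data)
    Fi[!band] <- 0
    Fd <- Fi - Fg
    if (!is.null(geometry)) {
      Ri <- euler_to_matrix(eul[1], eul[2], eul[3])
      fmi <- fftshift3(rotate_volume(wvol, t(Ri))$data) >= 0.5
      Fd[!fmi] <- 0
    }
    res[, i] <- Re(stats::fft(Fd, inverse = TRUE)) / prod(d) * msk
  }
  focus <- NULL
  scores <- matrix(0, n, k)
  if (!is.null(references)) {
    if (length(references) != k) stop("need one seed reference per class")
    for (c in seq_len(k)) {
      Fc <- stats::fft(references[[c]]$data)
      Fc[!band] <- 0
      rc <- (Re(stats::fft(Fc - Fg, inverse = TRUE)) / prod(d) * msk)
      nrc <- sqrt(sum(rc^2))
      for (i in seq_len(n)) {
        nri <- sqrt(sum(res[, i]^2))
        scores[i, c] <- if (nrc * nri > 0) sum(res[, i] * rc) / (nrc * nri) else 0
      }
    }
    assign <- max.col(scores, ties.method = "first")
  } else if (k == 1L) {
    assign <- rep(1L, n)
  } else {
    # focus on where the population actually varies
    vmap <- matrixStats_rowVars(res)
    inmask <- as.vector(msk > 0.5)
    thr <- stats::quantile(vmap[inmask], focus_quantile)
    focus_v <- vmap >= thr & inmask
    sc1 <- colMeans(res[focus_v, , drop = FALSE])
    set.seed(seed)
    assign <- stats::kmeans(sc1, centers = k, nstart = 10)$cluster
    # focused EM with leave-one-out class means
    for (it in seq_len(n_iter)) {
      mu <- matrix(0, sum(focus_v), k)
      pops <- tabulate(assign, k)
      for (c in seq_len(k)) {
        members <- which(assign == c)
        if (!length(members)) members <- which.min(sc1)
        mu[, c] <- rowMeans(res[focus_v, members, drop = FALSE])
      }
      for (c in seq_len(k)) for (i in seq_len(n)) {
        m <- mu[, c]
        if (assign[i] == c && pops[c] > 1L)
          m <- (m * pops[c] - res[focus_v, i]) / (pops[c] - 1L)
        nm <- sqrt(sum(m^2)); ni <- sqrt(sum(res[focus_v, i]^2))
        scores[i, c] <- if (nm * ni > 0) sum(res[focus_v, i] * m) / (nm * ni) else 0
      }
      new_assign <- max.col(scores, ties.method = "first")
      if (all(new_assign == assign) && it > 1) break
      assign <- new_assign
    }
    focus <- array(focus_v, d)
  }
  averages <- vector("list", k)
  for (c in seq_len(k)) {
    members <- which(assign == c)
    if (!length(members)) members <- which.max(scores[, c])
    averages[[c]] <- average_subtomograms(particles[members],
                                          table[members, , drop = FALSE],
                                          geometry)
  }
  list(assignments = assign, averages = averages,
       population = tabulate(assign, k), scores = scores, focus = focus)
}

# row variances without extra dependencies
matrixStats_rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}
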