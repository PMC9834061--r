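#' Impose helical symmetry on a map
#'
#' Averages the map over the helical symmetry operations (shift by
#' k * rise along z combined with rotation by k * twist about z) for all
#' integer k that keep the central `z_extent_fraction` of the box inside
#' the grid. Each voxel is normalized by the number of in-bounds
#' contributions, so the output lives on the same grid as the input.
#'
#' @param map a `tomo_volume` with the helix along +z.
#' @param params a [helical_params()].
#' @param z_extent_fraction central z fraction that must stay in-bounds
#'   under every applied operation (default 0.6).
#' @return symmetrized `tomo_volume`; attribute `"k_range"` records the
#'   operations used.
#' @export
symmetrize_helix <- function(map, params, z_extent_fraction = 0.6) {
  stopifnot_volume(map)
  stopifnot(inherits(params, "helical_params"))
  if (z_extent_fraction <= 0 || z_extent_fraction > 1)
    stop("z_extent_fraction must be in (0, 1]")
  if (params$rise < map$voxel_size)
    stop(sprintf("rise (%.2f A) below the voxel size (%.2f A): unresolvable symmetry",
                 params$rise, map$voxel_size))
  d <- dim(map$data)
  zlen <- d[3] * map$voxel_size
  kmax <- floor(((1 - z_extent_fraction) / 2 * zlen) / params$rise)
  ks <- -kmax:kmax
  acc <- array(0, d)
  cnt <- array(0, d)
  ones <- with_data(map, array(1, d))
  for (k in ks) {
    if (k == 0) {
      acc <- acc + map$data
      cnt <- cnt + 1
    } else {
      g <- rotate_volume(map, rot_z(k * params$twist),
                         shift = c(0, 0, k * params$rise))
      gm <- rotate_volume(ones, rot_z(k * params$twist),
                          shift = c(0, 0, k * params$rise))
      acc <- acc + g$data
      cnt <- cnt + gm$data
    }
  }
  out <- with_data(map, acc / pmax(cnt, 0.5))
  attr(out, "k_range") <- range(ks)
  out
}

# Exact (Fourier phase-ramp) shift of an array along z by `s` voxels.
# Wrap-around is confined to |s| voxels at the z faces, which callers
# exclude via their masks. Avoids the interpolation bias that favors
# integer-voxel rises in the symmetry objective.
fourier_shift_z <- function(x, s) {
  d <- dim(x)
  M <- matrix(x, d[1] * d[2], d[3])
  Fz <- t(stats::mvfft(t(M)))
  kz <- fft_freqs(d[3], 1)
  ph <- exp(-2i * pi * kz * s)
  Fz <- sweep(Fz, 2, ph, `*`)
  out <- Re(t(stats::mvfft(t(Fz), inverse = TRUE))) / d[3]
  array(out, d)
}

# Lean symmetrized copy for objective evaluation: fixed k set, rotation by
# trilinear resampling but exact Fourier z-shifts, no per-voxel count
# (callers restrict the correlation to a mask where all operations stay
# in-bounds and wrap-around cannot reach).
symmetrize_fixed_k <- function(map, rise, twist, ks) {
  acc <- array(0, dim(map$data))
  for (k in ks) {
    if (k == 0) acc <- acc + map$data
    else {
      rot <- rotate_volume(map, rot_z(k * twist))$data
      acc <- acc + fourier_shift_z(rot, k * rise / map$voxel_size)
    }
  }
  acc / length(ks)
}

#' Refine helical rise and twist by symmetry self-correlation
#'
#' Grid search maximizing the helical self-correlation of the map: for
#' each candidate (rise, twist), the map is compared with its helically
#' transformed copies (rotation by k * twist about z plus an exact Fourier
#' phase shift of k * rise along z, k = 1..`k_neighbors`) by normalized
#' correlation inside a separable cylindrical mask, and the per-k
#' correlations averaged. The z window of the mask is shrunk by the
#' largest candidate shift plus `edge_pad`, so neither wrap-around nor the
#' density fall-off at the box faces can bias the search toward small
#' rises. The grid peak is refined by local quadratic (parabolic)
#' interpolation; the full sampled surface is returned for diagnostics.
#'
#' @param map a `tomo_volume` containing a filament along z.
#' @param rise_range,twist_range numeric length-2 search intervals
#'   (Angstrom / degrees); default +/-15% and +/-10 degrees around
#'   `prior`.
#' @param rise_step,twist_step grid steps (default 0.1 A / 0.1 deg).
#' @param prior a [helical_params()] centering the default ranges.
#' @param mask_radius cylinder mask radius in Angstrom (default 50).
#' @param k_neighbors symmetry operations k = 1..k_neighbors averaged in
#'   the objective (default 2; reduced automatically when the box is too
#'   short).
#' @param edge_pad extra z-window margin in Angstrom guarding against
#'   edge fall-off (default 40, about one subunit).
#' @param min_spread "unresolved" error if the objective surface spread is
#'   below this (featureless maps; default 0.002).
#' @return list of class `helical_refine`: `params` (refined
#'   [helical_params()]), `objective` (matrix rise x twist), `rise_grid`,
#'   `twist_grid`, `value` (peak correlation).
#' @export
refine_helical_params <- function(map, prior = helical_params(27.5, -166.7),
                                  rise_range = prior$rise * c(0.85, 1.15),
                                  rise_step = 0.1,
                                  twist_range = prior$twist + c(-10, 10),
                                  twist_step = 0.1,
                                  mask_radius = 50,
                                  k_neighbors = 2,
                                  edge_pad = 40,
                                  min_spread = 0.002) {
  stopifnot_volume(map)
  d <- dim(map$data)
  vx <- map$voxel_size
  rises <- seq(rise_range[1], rise_range[2], by = rise_step)
  twists <- seq(twist_range[1], twist_range[2], by = twist_step)
  zlen <- d[3] * vx
  K <- k_neighbors
  while (K > 1 && (zlen - 2 * (K * max(rises) + edge_pad)) < 0.15 * zlen)
    K <- K - 1
  if ((zlen - 2 * (K * max(rises) + edge_pad)) < 2 * vx)
    stop("box too short along z for the requested rise range")

  # separable mask: soft disc D(x,y) x z-window Z(z)
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2; cz <- (d[3] - 1) / 2
  r <- sqrt(outer(((0:(d[1] - 1)) - cx)^2, ((0:(d[2] - 1)) - cy)^2, `+`)) * vx
  edge <- 2 * vx
  D <- 0.5 * (1 + cos(pi * (r - mask_radius) / edge))
  D[r <= mask_radius] <- 1
  D[r >= mask_radius + edge] <- 0
  half_z <- (zlen / 2 - K * max(rises) - edge_pad) / vx
  Z <- as.numeric(abs((0:(d[3] - 1)) - cz) <= half_z)

  ncols <- d[1] * d[2]
  nz <- d[3]
  X <- matrix(aperm(map$data, c(3, 1, 2)), nz, ncols)   # z runs down rows
  Dv <- as.vector(D)
  U <- X * Z                                           # map * Z per column
  U <- sweep(U, 2, Dv, `*`)                            # full mask applied
  S_M <- sum(Dv) * sum(Z)
  Sa <- sum(U)
  Saa <- sum(U * X)                                    # sum M * map^2
  Uf <- stats::mvfft(U)
  Zf <- stats::fft(Z)
  fz <- fft_freqs(nz, 1)

  obj <- matrix(NA_real_, length(rises), length(twists))
  va <- Saa - Sa^2 / S_M
  for (j in seq_along(twists)) {
    num_t <- vector("list", K); Pf_t <- vector("list", K); Qf_t <- vector("list", K)
    for (k in seq_len(K)) {
      rot <- rotate_volume(map, rot_z(k * twists[j]))$data
      H <- matrix(aperm(rot, c(3, 1, 2)), nz, ncols)
      Hf <- stats::mvfft(H)
      num_t[[k]] <- rowSums(Conj(Uf) * Hf)             # A(f), length nz
      Pf_t[[k]] <- stats::fft(as.numeric(H %*% Dv))
      Qf_t[[k]] <- stats::fft(as.numeric((H * H) %*% Dv))
    }
    for (i in seq_along(rises)) {
      cc <- 0
      for (k in seq_len(K)) {
        ph <- exp(-2i * pi * fz * (k * rises[i] / vx))
        num <- Re(sum(ph * num_t[[k]])) / nz
        Sb <- Re(sum(Conj(Zf) * Pf_t[[k]] * ph)) / nz
        Sbb <- Re(sum(Conj(Zf) * Qf_t[[k]] * ph)) / nz
        vb <- Sbb - Sb^2 / S_M
        den <- sqrt(max(va, 0) * max(vb, 0))
        cc <- cc + if (den > 0) (num - Sa * Sb / S_M) / den else 0
      }
      obj[i, j] <- cc / K
    }
  }
  if (max(obj) - min(obj) < min_spread)
    stop("unresolved: helical-symmetry objective is flat (featureless map?)")
  pk <- which(obj == max(obj), arr.ind = TRUE)[1, ]
  refine1 <- function(grid, vals, i) {
    if (i <= 1 || i >= length(grid)) return(grid[i])
    v <- vals
    den <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (den >= 0) return(grid[i])
    delta <- 0.5 * (v[i - 1] - v[i + 1]) / den
    grid[i] + max(min(delta, 0.5), -0.5) * (grid[2] - grid[1])
  }
  rise_hat <- refine1(rises, obj[, pk[2]], pk[1])
  twist_hat <- refine1(twists, obj[pk[1], ], pk[2])
  structure(list(params = helical_params(rise_hat, twist_hat),
                 objective = obj, rise_grid = rises, twist_grid = twists,
                 value = max(obj), peak_index = pk),
            class = "helical_refine")
}

#' @export
print.helical_refine <- function(x, ...) {
  cat(sprintf("<helical_refine> rise %.3f A, twist %.3f deg (peak corr %.4f; grid %d x %d)\n",
              x$params$rise, x$params$twist, x$value,
              length(x$rise_grid), length(x$twist_grid)))
  invisible(x)
}
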