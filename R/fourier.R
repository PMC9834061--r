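# Fourier-space helpers: frequency grids, soft low-pass filters, shell
# indexing for FSC and shell-wise reference weighting. All cutoffs are in
# Angstrom (resolution d); the corresponding spatial frequency is 1/d.

fft_freqs <- function(n, d) {
  # frequencies (1/A) in unshifted FFT layout
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / (n * d)
  k
}

# |k| array (1/A) for a grid of dim `dm` at voxel size `voxel`
kradius3 <- function(dm, voxel) {
  kx <- fft_freqs(dm[1], voxel)
  ky <- fft_freqs(dm[2], voxel)
  kz <- fft_freqs(dm[3], voxel)
  r2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  sqrt(r2)
}

kradius2 <- function(dm, voxel) {
  kx <- fft_freqs(dm[1], voxel)
  ky <- fft_freqs(dm[2], voxel)
  sqrt(outer(kx^2, ky^2, `+`))
}

# raised-cosine low-pass profile: 1 below k1, 0 above k2
soft_lowpass_profile <- function(kr, cutoff, edge_frac = 0.25) {
  kc <- 1 / cutoff
  k1 <- kc * (1 - edge_frac / 2)
  k2 <- kc * (1 + edge_frac / 2)
  w <- 0.5 * (1 + cos(pi * (kr - k1) / (k2 - k1)))
  w[kr <= k1] <- 1
  w[kr >= k2] <- 0
  w
}

#' Soft low-pass filter a volume
#'
#' Multiplies the Fourier transform by a raised-cosine profile falling from
#' 1 to 0 across a band centered on the cutoff frequency. Used to filter
#' external references (e.g. to 60 A) before alignment to avoid model bias.
#'
#' @param vol a `tomo_volume`.
#' @param cutoff resolution cutoff in Angstrom.
#' @param edge_frac relative width of the cosine edge (default 0.25).
#' @return filtered `tomo_volume`.
#' @export
lowpass_volume <- function(vol, cutoff, edge_frac = 0.25) {
  stopifnot_volume(vol)
  kr <- kradius3(dim(vol$data), vol$voxel_size)
  w <- soft_lowpass_profile(kr, cutoff, edge_frac)
  out <- Re(stats::fft(stats::fft(vol$data) * w, inverse = TRUE)) /
    length(vol$data)
  with_data(vol, out)
}

lowpass_image <- function(img, cutoff, pixel, edge_frac = 0.25) {
  kr <- kradius2(dim(img), pixel)
  w <- soft_lowpass_profile(kr, cutoff, edge_frac)
  Re(stats::fft(stats::fft(img) * w, inverse = TRUE)) / length(img)
}

# Integer shell index (0 = DC) per Fourier voxel, in units of the x-axis
# frequency step; shells beyond Nyquist of the smallest dim get NA.
fourier_shells <- function(dm, voxel) {
  kr <- kradius3(dm, voxel)
  dk <- 1 / (dm[1] * voxel)
  sh <- round(kr / dk)
  nmax <- floor(min(dm) / 2)
  sh[sh > nmax] <- NA
  sh
}

# Multiply a volume's Fourier shells by given per-shell weights
# (length = max shell + 1, shell 0 first). Used for FSC-weighted reference
# updates.
filter_by_shell <- function(vol, weights) {
  sh <- fourier_shells(dim(vol$data), vol$voxel_size)
  w <- array(0, dim(vol$data))
  idx <- !is.na(sh) & sh < length(weights)
  w[idx] <- weights[sh[idx] + 1L]
  out <- Re(stats::fft(stats::fft(vol$data) * w, inverse = TRUE)) /
    length(vol$data)
  with_data(vol, out)
}

# Soft-edged cylindrical mask (axis z), radius in Angstrom, cosine edge.
cylinder_mask <- function(dm, voxel, radius, edge = 2 * voxel,
                          z_fraction = 1) {
  cx <- (dm[1] - 1) / 2; cy <- (dm[2] - 1) / 2
  r <- sqrt(outer(((0:(dm[1] - 1)) - cx)^2, ((0:(dm[2] - 1)) - cy)^2, `+`)) *
    voxel
  m2 <- 0.5 * (1 + cos(pi * (r - radius) / edge))
  m2[r <= radius] <- 1
  m2[r >= radius + edge] <- 0
  zprof <- rep(1, dm[3])
  if (z_fraction < 1) {
    cz <- (dm[3] - 1) / 2
    half <- z_fraction * dm[3] / 2
    zd <- abs((0:(dm[3] - 1)) - cz)
    ew <- max(2, 0.05 * dm[3])
    zprof <- 0.5 * (1 + cos(pi * (zd - half) / ew))
    zprof[zd <= half] <- 1
    zprof[zd >= half + ew] <- 0
  }
  outer(m2, zprof)
}

# Soft-edged spherical mask, radius in Angstrom.
sphere_mask <- function(dm, voxel, radius, edge = 2 * voxel) {
  ax <- function(n) ((0:(n - 1)) - (n - 1) / 2)^2
  r <- sqrt(outer(outer(ax(dm[1]), ax(dm[2]), `+`), ax(dm[3]), `+`)) * voxel
  m <- 0.5 * (1 + cos(pi * (r - radius) / edge))
  m[r <= radius] <- 1
  m[r >= radius + edge] <- 0
  m
}

dim3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  d
}
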