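#' Weighted back-projection of aligned 2D images into 3D
#'
#' Each canonicalized image is smeared back along its viewing direction at
#' its azimuth about the helical (z) axis. Before back-projection the
#' transverse Fourier components of every image are weighted by the local
#' angular sampling density (arc spacing between neighboring projection
#' lines, capped at one Fourier pixel) so that anisotropic azimuthal
#' coverage is flattened; with uniform angles this reduces to the
#' classical ramp-filter weighting of single-axis tomography.
#'
#' @param stack an aligned, canonicalized [projection_stack()] whose meta
#'   has a `rot` column (azimuth, degrees).
#' @param nx,ny transverse output dimensions in voxels (default: the image
#'   transverse size).
#' @param weighting `"density"` (default) or `"none"`.
#' @param min_images below this count the result is flagged low
#'   confidence (default 50).
#' @return a `tomo_volume`; attribute `"low_confidence"` is TRUE when too
#'   few images contributed.
#' @export
reconstruct_3d <- function(stack, nx = NULL, ny = NULL,
                           weighting = c("density", "none"),
                           min_images = 50) {
  weighting <- match.arg(weighting)
  n <- n_images(stack)
  if (!n) stop("empty stack")
  if (is.null(stack$meta$rot)) stop("stack is not aligned (no rot column)")
  d <- dim(stack$images)
  if (is.null(nx)) nx <- d[2]
  if (is.null(ny)) ny <- d[2]
  imgs <- stack$images
  if (weighting == "density") {
    w <- density_weights(stack$meta$rot, d[2])
    for (i in seq_len(n)) {
      IM <- t(stats::mvfft(t(imgs[, , i])))
      IM <- sweep(IM, 2, w[, i], `*`)
      imgs[, , i] <- Re(t(stats::mvfft(t(IM), inverse = TRUE))) / d[2]
    }
  }
  out <- cpp_backproject_z(imgs, deg2rad(stack$meta$rot), rep(1 / n, n),
                           as.integer(nx), as.integer(ny))
  vol <- new_volume(out, stack$pixel_size)
  low <- n < min_images
  if (low)
    warning(sprintf("only %d images back-projected (min %d): low-confidence map",
                    n, min_images))
  attr(vol, "low_confidence") <- low
  vol
}

# Per-image transverse Fourier weights: w_i(k) = min(|k_px| * dalpha_i, 1)
# where dalpha_i is the angular gap (radians, lines mod 180 degrees)
# around projection i; shared DC is down-weighted by the image count.
density_weights <- function(rot_deg, nt) {
  ang <- (rot_deg %% 180) * pi / 180
  n <- length(ang)
  o <- order(ang)
  gaps <- numeric(n)
  if (n == 1) {
    gaps[] <- pi
  } else {
    s <- ang[o]
    nb <- diff(c(s[n] - pi, s))        # gap below each sorted line
    na_ <- diff(c(s, s[1] + pi))       # gap above
    gaps[o] <- (nb + na_) / 2
  }
  kpx <- abs(fft_freqs(nt, 1)) * nt    # 0 .. nt/2 in Fourier pixels
  w <- outer(kpx, gaps, function(k, g) pmin(k * g, 1))
  w[1, ] <- 1 / n
  w
}

#' Fourier shell correlation between two half-maps
#'
#' Shell-wise normalized cross-correlation of the Fourier coefficients of
#' two independent half-reconstructions (split by filament, never by
#' segment, so inter-segment correlations cannot inflate the curve). The
#' resolution is the spatial frequency at which the curve first crosses
#' the threshold (default 0.143), linearly interpolated; if the curve
#' never crosses, resolution is the Nyquist limit (2 voxels).
#'
#' @param half_a,half_b `tomo_volume`s on identical grids.
#' @param mask optional soft real-space mask (array) applied to both.
#' @param threshold FSC resolution criterion (default 0.143; 0.5 can be
#'   configured).
#' @return list with `freq` (1/Angstrom), `fsc`, `resolution` (Angstrom),
#'   `threshold`, `n_shells`; class `fsc_curve`.
#' @export
compute_fsc <- function(half_a, half_b, mask = NULL, threshold = 0.143) {
  stopifnot_volume(half_a); stopifnot_volume(half_b)
  if (!identical(dim(half_a$data), dim(half_b$data)))
    stop("half-maps must share a grid")
  a <- half_a$data; b <- half_b$data
  if (!is.null(mask)) { a <- a * mask; b <- b * mask }
  fa <- stats::fft(a); fb <- stats::fft(b)
  sh <- fourier_shells(dim(a), half_a$voxel_size)
  ok <- !is.na(sh)
  shv <- as.integer(sh[ok]) + 1L
  num <- Re(fa[ok] * Conj(fb[ok]))
  pa <- Mod(fa[ok])^2
  pb <- Mod(fb[ok])^2
  s_num <- tapply_sum(num, shv)
  s_pa <- tapply_sum(pa, shv)
  s_pb <- tapply_sum(pb, shv)
  fsc <- s_num / sqrt(pmax(s_pa * s_pb, .Machine$double.eps))
  fsc <- pmax(pmin(fsc, 1), -1)
  nshell <- length(fsc)
  dk <- 1 / (dim(a)[1] * half_a$voxel_size)
  freq <- (seq_len(nshell) - 1L) * dk
  res <- 2 * half_a$voxel_size
  cross <- which(fsc < threshold & seq_along(fsc) > 1L)
  if (length(cross)) {
    i <- cross[1]
    f0 <- freq[i - 1]; f1 <- freq[i]
    v0 <- fsc[i - 1]; v1 <- fsc[i]
    fc <- f0 + (v0 - threshold) / pmax(v0 - v1, 1e-12) * (f1 - f0)
    res <- 1 / fc
  }
  structure(list(freq = freq, fsc = as.numeric(fsc), resolution = res,
                 threshold = threshold, n_shells = nshell),
            class = "fsc_curve")
}

tapply_sum <- function(x, idx) {
  as.numeric(rowsum(x, idx, reorder = TRUE))
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells; resolution %.2f A at FSC = %.3f\n",
              x$n_shells, x$resolution, x$threshold))
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, ...) {
  graphics::plot(x$freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  graphics::abline(h = x$threshold, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
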