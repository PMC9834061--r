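#' Filament centerline traces
#'
#' A filament trace is an ordered polyline of control points (Angstrom)
#' through which the package interpolates a smooth centerline (natural
#' cubic splines per coordinate on the chord-length parameter), with local
#' frames propagated by parallel transport so that the frame never twists
#' artificially around the curve.
#'
#' @param points n x 3 numeric matrix of control points in Angstrom
#'   (>= 2 rows, consecutive rows distinct).
#' @param filament_id identifier carried into segment tables.
#' @param source_volume_id optional identifier of the parent tomogram.
#' @return a `filament_trace` object.
#' @export
filament_trace <- function(points, filament_id = 1L, source_volume_id = NA) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("a trace needs an n x 3 matrix with at least 2 control points")
  steps <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(steps < 1e-9)) stop("consecutive control points must be distinct")
  structure(list(points = points, filament_id = filament_id,
                 source_volume_id = source_volume_id),
            class = "filament_trace")
}

# Dense arc-length sampling of a trace with parallel-transport frames.
# Returns positions P, unit tangents T, transported normals N1, N2 and the
# arc-length vector `arc` (step ~ `ds` Angstrom).
trace_frames <- function(trace, ds = 1.5) {
  pts <- trace$points
  tpar <- c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                                    pts[-nrow(pts), , drop = FALSE])^2))))
  fx <- stats::splinefun(tpar, pts[, 1], method = "natural")
  fy <- stats::splinefun(tpar, pts[, 2], method = "natural")
  fz <- stats::splinefun(tpar, pts[, 3], method = "natural")
  nt <- max(64L, ceiling(4 * max(tpar) / ds))
  tt <- seq(0, max(tpar), length.out = nt)
  P0 <- cbind(fx(tt), fy(tt), fz(tt))
  arc0 <- c(0, cumsum(sqrt(rowSums(diff(P0)^2))))
  L <- arc0[length(arc0)]
  # re-sample uniformly in arc length
  ns <- max(2L, ceiling(L / ds) + 1L)
  s <- seq(0, L, length.out = ns)
  tq <- stats::approx(arc0, tt, xout = s, rule = 2)$y
  P <- cbind(fx(tq), fy(tq), fz(tq))
  Tm <- cbind(fx(tq, deriv = 1), fy(tq, deriv = 1), fz(tq, deriv = 1))
  Tm <- Tm / sqrt(rowSums(Tm^2))
  # parallel transport of the first normal
  N1 <- matrix(0, ns, 3)
  t1 <- Tm[1, ]
  a <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n <- a - sum(a * t1) * t1
  N1[1, ] <- n / sqrt(sum(n^2))
  if (ns > 1) {
    for (i in 2:ns) {
      n <- N1[i - 1, ] - sum(N1[i - 1, ] * Tm[i, ]) * Tm[i, ]
      nn <- sqrt(sum(n^2))
      if (nn < 1e-9) n <- N1[i - 1, ] else n <- n / nn
      N1[i, ] <- n
    }
  }
  N2 <- cbind(Tm[, 2] * N1[, 3] - Tm[, 3] * N1[, 2],
              Tm[, 3] * N1[, 1] - Tm[, 1] * N1[, 3],
              Tm[, 1] * N1[, 2] - Tm[, 2] * N1[, 1])
  list(s = s, P = P, T = Tm, N1 = N1, N2 = N2, length = L)
}

# Interpolate frames at arbitrary arc positions (vector `at`, Angstrom).
frames_at <- function(fr, at) {
  interp_rows <- function(M) {
    apply(M, 2, function(col) stats::approx(fr$s, col, xout = at, rule = 2)$y)
  }
  P <- interp_rows(fr$P)
  Tm <- interp_rows(fr$T)
  N1 <- interp_rows(fr$N1)
  if (length(at) == 1L) {
    P <- matrix(P, 1); Tm <- matrix(Tm, 1); N1 <- matrix(N1, 1)
  }
  Tm <- Tm / sqrt(rowSums(Tm^2))
  # re-orthogonalize transported normal against the tangent
  N1 <- N1 - rowSums(N1 * Tm) * Tm
  N1 <- N1 / sqrt(rowSums(N1^2))
  N2 <- cbind(Tm[, 2] * N1[, 3] - Tm[, 3] * N1[, 2],
              Tm[, 3] * N1[, 1] - Tm[, 1] * N1[, 3],
              Tm[, 1] * N1[, 2] - Tm[, 2] * N1[, 1])
  list(P = P, T = Tm, N1 = N1, N2 = N2)
}

# Reverse the direction of a trace (models picking a filament "backwards").
reverse_trace <- function(trace) {
  filament_trace(trace$points[nrow(trace$points):1, , drop = FALSE],
                 filament_id = trace$filament_id,
                 source_volume_id = trace$source_volume_id)
}
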