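#' 2D classification without orientation sampling
#'
#' K-class classification of aligned (canonicalized) projection images by
#' alternating correlation-based assignment and class averaging, with the
#' alignments frozen ("without sampling"). Each class average gets a
#' contrast score — the variance of the average inside a central band mask
#' covering the filament — used to select classes with visible features.
#'
#' @param stack an aligned [projection_stack()] (canonical frame).
#' @param k number of classes (1 <= k <= number of images).
#' @param n_iter assignment/averaging iterations.
#' @param seed RNG seed for the initial random assignment.
#' @param band_radius half-width (Angstrom) of the filament band mask used
#'   for the contrast score.
#' @return list with `assignments` (integer per image), `averages`
#'   (array na x nt x k), `population`, `contrast` and the input `stack`
#'   with `class_id` filled into its metadata.
#' @export
classify_2d <- function(stack, k = 8, n_iter = 10, seed = 1L,
                        band_radius = 60) {
  n <- n_images(stack)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop(sprintf("k (%d) exceeds the number of images (%d)", k, n))
  d <- dim(stack$images)
  vx <- stack$pixel_size
  imgs <- array(0, d)
  for (i in seq_len(n)) {
    im <- stack$images[, , i] - mean(stack$images[, , i])
    nr <- sqrt(sum(im^2))
    imgs[, , i] <- if (nr > 0) im / nr else im
  }
  set.seed(seed)
  assign <- sample(rep_len(seq_len(k), n))
  flat <- matrix(imgs, d[1] * d[2], n)
  for (it in seq_len(n_iter)) {
    avg <- matrix(0, d[1] * d[2], k)
    for (c in seq_len(k)) {
      members <- which(assign == c)
      if (!length(members)) {
        # re-seed an empty class with the worst-matching image
        members <- which.min(apply(flat, 2, function(x) max(abs(x))))
      }
      a <- rowMeans(flat[, members, drop = FALSE])
      a <- a - mean(a)
      nr <- sqrt(sum(a^2))
      avg[, c] <- if (nr > 0) a / nr else a
    }
    scores <- crossprod(flat, avg)          # n x k correlations
    new_assign <- max.col(scores, ties.method = "first")
    if (all(new_assign == assign) && it > 1) break
    assign <- new_assign
  }
  averages <- array(avg, c(d[1], d[2], k))
  ct <- (d[2] - 1) / 2
  band <- abs((seq_len(d[2]) - 1) - ct) * vx <= band_radius
  contrast <- vapply(seq_len(k), function(c) {
    stats::var(as.vector(averages[, band, c]))
  }, numeric(1))
  stack$meta$class_id <- assign
  list(assignments = assign, averages = averages,
       population = tabulate(assign, k), contrast = contrast, stack = stack)
}

#' Select 2D classes with visible features
#'
#' Automates the visual "classes with visible features" selection as a
#' contrast floor: classes whose contrast score falls below
#' `min_contrast_frac` times the median class contrast are dropped as
#' featureless. A fixed top-`fraction` cut can be requested instead, but
#' discards segments even when every class shows features, which biases
#' the azimuthal coverage of the final reconstruction.
#'
#' @param classification result of [classify_2d()].
#' @param min_contrast_frac adaptive contrast floor as a fraction of the
#'   median class contrast (default 0.4).
#' @param fraction optional fixed fraction of classes to keep (overrides
#'   the adaptive floor when given).
#' @param keep,drop optional class-id overrides.
#' @return integer vector of selected class ids.
#' @export
select_classes <- function(classification, min_contrast_frac = 0.4,
                           fraction = NULL,
                           keep = integer(0), drop = integer(0)) {
  contrast <- classification$contrast
  k <- length(contrast)
  if (!is.null(fraction)) {
    n_keep <- max(1L, round(fraction * k))
    sel <- order(contrast, decreasing = TRUE)[seq_len(n_keep)]
  } else {
    sel <- which(contrast >= min_contrast_frac * stats::median(contrast))
    if (!length(sel)) sel <- which.max(contrast)
  }
  sel <- union(setdiff(sel, drop), keep)
  sort(sel)
}
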