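#' Render a straight helical reference map
#'
#' Builds a noise-free two-stranded helical filament along +z at the given
#' helical parameters, for use as the initial alignment reference (the
#' equivalent of the external actin reference in the workflow this package
#' implements). Low-pass filter it (e.g. to 60 A) before alignment to
#' avoid model bias; the canonical F-actin parameters (27.5 A, -166.7 deg)
#' are the package's default prior, deliberately distinct from any
#' specimen under study.
#'
#' @param params [helical_params()] of the reference helix.
#' @param box box size in voxels.
#' @param voxel_size voxel size in Angstrom.
#' @param subunit optional subunit `tomo_volume` (default: two-lobe, 45 A).
#' @param helix_radius subunit center radius in Angstrom.
#' @param two_strands render the second strand (default TRUE).
#' @param lowpass optional low-pass cutoff in Angstrom.
#' @return a `tomo_volume`.
#' @export
make_helical_reference <- function(params = helical_params(27.5, -166.7),
                                   box = 64, voxel_size = 5.36,
                                   subunit = NULL, helix_radius = 15,
                                   two_strands = TRUE, lowpass = NULL) {
  if (is.null(subunit))
    subunit <- make_subunit_model("two_lobe", 45, voxel_size)
  ctr <- (box - 1) / 2 * voxel_size
  zlen <- (box - 1) * voxel_size
  tr <- filament_trace(cbind(ctr, ctr, seq(0, zlen, length.out = 5)))
  rf <- render_filament(tr, params, subunit, dim = rep(box, 3),
                        voxel_size = voxel_size, two_strands = two_strands,
                        helix_radius = helix_radius)
  vol <- rf$volume
  if (!is.null(lowpass)) vol <- lowpass_volume(vol, lowpass)
  vol
}

# Oriented extraction of every segment of `table` from its source volume.
# Returns list(subvols, kept): segments whose needed source support falls
# outside the tomogram are dropped.
extract_oriented_segments <- function(volumes, table, box, pad_radius = 60) {
  subvols <- list()
  kept <- integer(0)
  for (i in seq_len(nrow(table))) {
    src <- table$source_volume_id[i]
    vol <- volumes[[src]]
    d <- dim(vol$data)
    ctr <- c(table$center_x[i], table$center_y[i], table$center_z[i])
    tang <- c(table$tangent_x[i], table$tangent_y[i], table$tangent_z[i])
    half_ax <- (box / 2) * vol$voxel_size
    ends <- rbind(ctr + half_ax * tang, ctr - half_ax * tang)
    lo <- vol$origin
    hi <- vol$origin + (d - 1) * vol$voxel_size
    # the segment's axial span, padded transversely, must stay inside in
    # x and y; in z the filament support (pad) around the ends must fit
    pad <- c(pad_radius, pad_radius, min(pad_radius, (hi[3] - lo[3]) / 2 - 1))
    ok <- all(ctr >= lo & ctr <= hi) &&
      all(t(ends) >= lo + pad + 1e-6) && all(t(ends) <= hi - pad - 1e-6)
    if (!ok) next
    R <- rotation_between(tang, c(0, 0, 1))
    # choose the free in-plane azimuth so the projection direction (+y of
    # the oriented box) coincides with the beam axis: the projected slab
    # is then the fully sampled tilt-0 central section and the missing
    # wedge cannot streak the images or bias the twist search
    v <- R %*% c(0, 0, 1)
    if (sqrt(v[1]^2 + v[2]^2) > 0.1) {
      delta <- 90 - atan2(v[2], v[1]) * 180 / pi
      R <- rot_z(delta) %*% R
    }
    kept <- c(kept, i)
    subvols[[length(subvols) + 1L]] <- resample_oriented(vol, ctr, R, box)
  }
  list(subvols = subvols, kept = kept)
}

#' Iterative helical reconstruction of filament segments
#'
#' The full filament-analysis loop: segments are cut from the tomograms
#' along their traces, rotated onto the z axis, centered on a featureless
#' cylinder, projected into 2D, aligned against reference projections,
#' back-projected into 3D, and the helical rise/twist refined on the
#' reconstruction; the symmetrized, FSC-weighted map becomes the reference
#' of the next iteration (three iterations by default). In the final round
#' a 2D classification with frozen alignments selects classes with visible
#' features, the surviving segments are locally re-aligned at finer
#' angular steps, and the helical parameters are re-optimized on the final
#' reconstruction. Polarity votes are computed per filament but (by
#' default) not applied.
#'
#' @param config a [run_config()]; `n_iterations`, `box_size`,
#'   `intersegment_distance`, `lowpass_reference` and `rng_seed` are used.
#' @param volumes list of tomogram `tomo_volume`s.
#' @param traces list of [filament_trace()]s whose `source_volume_id`
#'   indexes into `volumes`.
#' @param reference optional initial reference `tomo_volume` (filament
#'   along +z); default: [make_helical_reference()] with the F-actin prior,
#'   low-passed to `config$lowpass_reference`.
#' @param prior [helical_params()] prior for the symmetry search (default
#'   canonical F-actin: 27.5 A, -166.7 deg).
#' @param slab_fraction projected slab depth fraction (default 1/3).
#' @param rot_step global azimuthal search step in degrees.
#' @param psi_range,psi_step in-plane search range/step in degrees.
#' @param k_classes,min_contrast_frac 2D classification settings for the
#'   final round (see [classify_2d()] and [select_classes()]).
#' @param reference_mode how the alignment reference is updated between
#'   iterations: `"model"` (default) re-renders a clean parametric helix
#'   at the refined rise/twist, low-passed at the measured FSC resolution
#'   — the measured parameters remain data-driven (they come from the
#'   reconstruction, and are insensitive to the reference's own
#'   parameters), while the reference stays noise-free; `"map"` uses the
#'   symmetrized reconstruction itself, as in reference-based refinement
#'   of real data where no parametric density model is trusted.
#' @param cylinder_radius centering cylinder radius in Angstrom.
#' @param mask_radius cylindrical mask radius (Angstrom) for FSC and the
#'   symmetry objective.
#' @param verbose print per-iteration progress.
#' @return an object of class `helical_recon`; see [print.helical_recon()].
#' @export
run_filament_pipeline <- function(config, volumes, traces, reference = NULL,
                                  prior = helical_params(27.5, -166.7),
                                  slab_fraction = 1 / 3, rot_step = 4,
                                  psi_range = 15, psi_step = 5,
                                  k_classes = 8, min_contrast_frac = 0.4,
                                  reference_mode = c("model", "map"),
                                  cylinder_radius = 40, mask_radius = 50,
                                  verbose = TRUE) {
  reference_mode <- match.arg(reference_mode)
  if (!length(traces) || !length(volumes))
    stop("no segments: the pipeline needs at least one trace and volume")
  box <- config$box_size
  vx <- volumes[[1]]$voxel_size
  set.seed(config$rng_seed)
  table <- do.call(rbind, lapply(traces, segment_trace,
                                 spacing = config$intersegment_distance))
  if (!nrow(table)) stop("no segments")
  if (is.null(reference)) {
    reference <- make_helical_reference(prior, box, vx,
                                        lowpass = config$lowpass_reference)
  } else {
    reference <- lowpass_volume(reference, config$lowpass_reference)
  }
  params_cur <- prior
  history <- list()
  fsc <- NULL
  stack <- NULL
  kept <- NULL
  log_run_event("run_filament_pipeline", n_filaments = length(traces),
                n_segments = nrow(table), box = box, voxel_size = vx,
                seed = config$rng_seed, n_iterations = config$n_iterations)

  for (it in seq_len(config$n_iterations)) {
    ext <- extract_oriented_segments(volumes, table, box)
    if (!length(ext$subvols)) stop("no segments inside the volumes")
    if (it == 1L) {
      # cylinder centering; fold the measured offsets back into the table
      for (j in seq_along(ext$subvols)) {
        i <- ext$kept[j]
        cen <- center_on_cylinder(ext$subvols[[j]], cylinder_radius)
        tang <- c(table$tangent_x[i], table$tangent_y[i], table$tangent_z[i])
        R <- rotation_between(tang, c(0, 0, 1))
        dxyz <- t(R) %*% c(cen$shift, 0)
        table$center_x[i] <- table$center_x[i] + dxyz[1]
        table$center_y[i] <- table$center_y[i] + dxyz[2]
        table$center_z[i] <- table$center_z[i] + dxyz[3]
      }
      ext <- extract_oriented_segments(volumes, table, box)
    }
    kept <- ext$kept
    meta <- table[kept, c("particle_id", "filament_id", "arc_position"),
                  drop = FALSE]
    stack <- project_segments(ext$subvols, slab_fraction, meta = meta)
    stack <- align_2d(stack, reference, rot_step = rot_step,
                      psi_range = psi_range, psi_step = psi_step,
                      max_shift = 3 * vx,
                      max_axial_shift = params_cur$rise / 2)
    # fine local polish: the 2D projections of a twisted filament couple
    # azimuth and axial shift, so coarse-grid quantization errors correlate
    # and distort the apparent lattice; a 1-degree local pass removes them
    stack <- align_2d_local(stack, reference, rot_range = 2 * rot_step,
                            rot_step = 1, psi_range = psi_step, psi_step = 2,
                            max_shift = 2 * vx,
                            max_axial_shift = params_cur$rise / 2)
    if (it == 1L) {
      # the 60 A external reference carries no lattice striations, so the
      # measured axial shifts of round 1 are register noise; project them
      # onto a coherent helical register at the prior rate (one phase per
      # filament, intra-filament phase relations fixed by the traced arc
      # positions) so the first reconstruction already has a lattice for
      # the next reference. Later rounds align against lattice-bearing
      # references and their measured shifts are used as-is.
      reg <- estimate_register_rate(stack$meta, prior$rise, range_frac = 0)
      stack$meta$shift_axial <- reg$shift_axial
    }
    canon <- canonicalize_stack(stack)
    halves <- filament_halves(canon$meta$filament_id)
    map_a <- reconstruct_3d(subset_stack(canon, halves == 1), box, box,
                            min_images = 1)
    map_b <- reconstruct_3d(subset_stack(canon, halves == 2), box, box,
                            min_images = 1)
    fsc_mask <- cylinder_mask(rep(box, 3), vx, mask_radius + 10,
                              z_fraction = 0.85)
    fsc <- compute_fsc(map_a, map_b, mask = fsc_mask)
    map <- reconstruct_3d(canon, box, box, min_images = 1)
    # search window anchored on the external prior so a noisy early
    # estimate cannot drag later iterations out of range
    ref_coarse <- refine_helical_params(map, prior = prior,
                                        rise_step = 0.5, twist_step = 0.5,
                                        mask_radius = mask_radius,
                                        k_neighbors = 3)
    ref_fine <- refine_helical_params(
      map, prior = prior,
      rise_range = ref_coarse$params$rise + c(-0.6, 0.6), rise_step = 0.1,
      twist_range = ref_coarse$params$twist + c(-1.2, 1.2), twist_step = 0.1,
      mask_radius = mask_radius, k_neighbors = 3)
    params_cur <- ref_fine$params
    # update the reference: helical symmetry is imposed with the refined
    # values once the symmetry search is confident (clear interior peak),
    # with the prior until then — symmetry "applied" while unresolved,
    # "optimized" after
    sym_params <- if (refine_confident(ref_coarse)) params_cur else prior
    cutoff <- max(fsc$resolution, 20)
    if (reference_mode == "model") {
      reference <- make_helical_reference(sym_params, box, vx,
                                          lowpass = cutoff)
    } else {
      sym <- symmetrize_helix(map, sym_params)
      reference <- filtered_reference(sym, cutoff, mask_radius)
    }
    history[[it]] <- data.frame(iteration = it, rise = params_cur$rise,
                                twist = params_cur$twist,
                                resolution = fsc$resolution,
                                n_images = n_images(stack))
    if (verbose)
      message(sprintf("iteration %d: rise %.2f A, twist %.2f deg, FSC resolution %.1f A (%d segments)",
                      it, params_cur$rise, params_cur$twist, fsc$resolution,
                      n_images(stack)))
  }

  # final round: 2D classification (frozen alignments) + class selection,
  # local re-alignment of the survivors, final reconstruction and symmetry
  # re-optimization
  canon <- canonicalize_stack(stack)
  cls <- classify_2d(canon, k = min(k_classes, n_images(canon)),
                     seed = config$rng_seed, band_radius = mask_radius + 10)
  selected <- select_classes(cls, min_contrast_frac = min_contrast_frac)
  keep_img <- cls$assignments %in% selected
  stack$meta$class_id <- cls$assignments
  sub <- subset_stack(stack, keep_img)
  sub <- align_2d_local(sub, reference, rot_range = 2 * rot_step,
                        rot_step = 1,
                        psi_range = psi_step, psi_step = 2,
                        max_shift = 2 * vx,
                        max_axial_shift = params_cur$rise / 2)
  canon_f <- canonicalize_stack(sub)
  halves <- filament_halves(canon_f$meta$filament_id)
  map_a <- reconstruct_3d(subset_stack(canon_f, halves == 1), box, box,
                          min_images = 1)
  map_b <- reconstruct_3d(subset_stack(canon_f, halves == 2), box, box,
                          min_images = 1)
  fsc_mask <- cylinder_mask(rep(box, 3), vx, mask_radius + 10,
                            z_fraction = 0.85)
  fsc <- compute_fsc(map_a, map_b, mask = fsc_mask)
  map <- reconstruct_3d(canon_f, box, box, min_images = 1)
  ref_coarse <- refine_helical_params(map, prior = prior,
                                      rise_step = 0.5, twist_step = 0.5,
                                      mask_radius = mask_radius,
                                      k_neighbors = 3)
  ref_fine <- refine_helical_params(
    map, prior = prior,
    rise_range = ref_coarse$params$rise + c(-0.6, 0.6), rise_step = 0.1,
    twist_range = ref_coarse$params$twist + c(-1.2, 1.2), twist_step = 0.1,
    mask_radius = mask_radius, k_neighbors = 3)
  params_cur <- ref_fine$params
  final_map <- symmetrize_helix(map, params_cur)
  pol <- vote_polarity(stack$meta)

  alignment <- cbind(table[kept, setdiff(names(table), "particle_id"),
                           drop = FALSE],
                     stack$meta)
  history <- do.call(rbind, history)
  structure(list(
    map = final_map, raw_map = map, refined = params_cur, prior = prior,
    refine = ref_fine, fsc = fsc, resolution = fsc$resolution,
    n_particles_used = n_images(canon_f), n_segments = nrow(table),
    alignment = alignment, classes = cls[c("population", "contrast")],
    selected_classes = selected, polarity = pol$votes, history = history,
    config = config, reference = reference),
    class = "helical_recon")
}

# A symmetry search is trusted when its grid peak is strictly interior to
# the search window (not pinned at an edge) and the surface has a clear
# spread.
refine_confident <- function(rf, min_spread = 0.05, edge_margin = 2) {
  pk <- rf$peak_index
  interior <- pk[1] > edge_margin &&
    pk[1] <= length(rf$rise_grid) - edge_margin &&
    pk[2] > edge_margin && pk[2] <= length(rf$twist_grid) - edge_margin
  interior && (max(rf$objective) - min(rf$objective) >= min_spread)
}

# Estimate the lattice register of aligned segments: one global axial
# lattice rate (rise, Angstrom) plus one phase per filament, by circular
# regression of the measured per-segment phases (shift_axial +
# arc_position) mod rate, score-weighted. Because every box is phase-
# matched to the reference independently, the measured phases carry the
# data's true lattice rate even when the reference lattice is slightly
# off. Returns the rate, per-filament phases, and register-consistent
# axial shifts wrap(c_f - s_i, rate) for every segment.
estimate_register_rate <- function(meta, rise_prior, range_frac = 0.07,
                                   step = 0.05, conc_threshold = 0.1) {
  s <- meta$arc_position
  dz <- meta$shift_axial
  w <- pmax(meta$score, 1e-6)
  fid <- meta$filament_id
  rates <- seq(rise_prior * (1 - range_frac), rise_prior * (1 + range_frac),
               by = step)
  conc_at <- function(r, shifts) {
    th <- 2 * pi * (shifts + s) / r
    z <- w * exp(1i * th)
    sum(vapply(split(z, fid), function(zz) Mod(sum(zz)), numeric(1))) / sum(w)
  }
  # null-correct against the alias produced by the regular segment
  # spacing alone (rates near spacing/n look concentrated even for
  # uninformative shifts); the corrected profile peaks only where the
  # measured shifts genuinely track the lattice
  conc <- vapply(rates, conc_at, numeric(1), shifts = dz) -
    vapply(rates, conc_at, numeric(1), shifts = 0 * dz)
  i <- which.max(conc)
  rate <- rates[i]
  if (i > 1 && i < length(rates)) {
    den <- conc[i - 1] - 2 * conc[i] + conc[i + 1]
    if (den < 0)
      rate <- rate + max(min(0.5 * (conc[i - 1] - conc[i + 1]) / den, 0.5),
                         -0.5) * step
  }
  # with a striation-free reference (e.g. the 60 A first round) the
  # measured phases are noise; fall back to the prior rate, which still
  # imposes a coherent register (the absolute rate refines on later
  # rounds once the reference carries the lattice)
  if (max(conc) < conc_threshold) rate <- rise_prior
  th <- 2 * pi * (dz + s) / rate
  z <- w * exp(1i * th)
  phase <- vapply(split(z, fid), function(zz) Arg(sum(zz)), numeric(1)) *
    rate / (2 * pi)
  c_f <- phase[as.character(fid)]
  upd <- (c_f - s) %% rate
  upd[upd > rate / 2] <- upd[upd > rate / 2] - rate
  list(rate = rate, phases = phase, shift_axial = unname(upd),
       concentration = max(conc))
}

filament_halves <- function(fids) {
  u <- unique(fids)
  h <- stats::setNames(rep_len(1:2, length(u)), u)
  unname(h[as.character(fids)])
}

subset_stack <- function(stack, idx) {
  projection_stack(stack$images[, , idx, drop = FALSE], stack$pixel_size,
                   stack$meta[idx, , drop = FALSE])
}

# Updated-reference filtering: soft low-pass at the measured FSC
# resolution (floored at ~4 voxels) plus a soft cylindrical mask. The
# symmetrized map entering here has its helical lattice amplified by
# symmetry averaging, so a fixed-cutoff filter (rather than strict
# per-shell FSC weighting) keeps the weak but real layer-line signal that
# locks the axial register of the next alignment round.
filtered_reference <- function(map, cutoff, mask_radius = 50) {
  cutoff <- max(cutoff, 4 * map$voxel_size)
  out <- lowpass_volume(map, cutoff)
  m <- cylinder_mask(dim(out$data), out$voxel_size, mask_radius + 15,
                     z_fraction = 0.95)
  with_data(out, out$data * m)
}

#' @export
print.helical_recon <- function(x, ...) {
  cat("Helical reconstruction from 2D-projected filament segments\n")
  cat(sprintf("  segments used: %d of %d (classes %s)\n",
              x$n_particles_used, x$n_segments,
              paste(x$selected_classes, collapse = ",")))
  cat(sprintf("  refined helical parameters: rise %.2f A, twist %.2f deg\n",
              x$refined$rise, x$refined$twist))
  cat(sprintf("  FSC resolution: %.1f A at threshold %.3f\n",
              x$resolution, x$fsc$threshold))
  invisible(x)
}

#' @export
summary.helical_recon <- function(object, ...) {
  cat("Iterative helical reconstruction\n\n")
  cat(sprintf("Prior: %s\n", format(object$prior)))
  cat(sprintf("Refined: %s\n\n", format(object$refined)))
  cat("Per-iteration history:\n")
  print(object$history, row.names = FALSE)
  cat(sprintf("\nFSC resolution (threshold %.3f): %.1f A\n",
              object$fsc$threshold, object$resolution))
  cat(sprintf("Polarity votes: %d/%d filaments 'up' (mean confidence %.2f; diagnostic only)\n",
              sum(object$polarity$polarity == "up"), nrow(object$polarity),
              mean(object$polarity$confidence)))
  invisible(object)
}

#' @export
coef.helical_recon <- function(object, ...) {
  c(rise = object$refined$rise, twist = object$refined$twist)
}

#' @export
plot.helical_recon <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$fsc, main = "half-map FSC")
  graphics::image(x$refine$rise_grid, x$refine$twist_grid, x$refine$objective,
                  xlab = "rise (A)", ylab = "twist (deg)",
                  main = "symmetry objective", col = grDevices::hcl.colors(64))
  graphics::points(x$refined$rise, x$refined$twist, pch = 3)
  mid <- dim(x$map$data)[2] %/% 2
  graphics::image(x$map$data[, mid, ], xlab = "x", ylab = "z",
                  main = "map central slice", col = grDevices::gray.colors(64))
  invisible(x)
}
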