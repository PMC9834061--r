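#' Per-filament polarity voting
#'
#' Each aligned segment carries a polarity estimate ("up" when its
#' in-plane angle solution sits on the psi ~ 0 branch, "down" on the
#' psi ~ 180 branch, i.e. the filament appears end-flipped). Segments of
#' the same filament vote; the majority defines the filament polarity and
#' the majority fraction its confidence. Voting is diagnostic by default —
#' alignments are returned unchanged, matching the workflow this package
#' implements, where voting results were not applied because the
#' resolution did not support confident polarity assignment. With
#' `apply = TRUE`, minority segments are flipped onto the majority branch
#' (psi + 180, azimuth negated, axial shift negated).
#'
#' @param table segment/alignment metadata with `filament_id` and either a
#'   `polarity_flag` ("up"/"down") or a `psi` column.
#' @param apply flip minority segments (default FALSE).
#' @return list with `votes` (per filament: polarity, confidence,
#'   n_segments, singleton flag) and `table` (unchanged unless
#'   `apply = TRUE`).
#' @export
vote_polarity <- function(table, apply = FALSE) {
  if (is.null(table$filament_id)) stop("table needs a filament_id column")
  if (is.null(table$polarity_flag)) {
    if (is.null(table$psi)) stop("table needs polarity_flag or psi")
    table$polarity_flag <- ifelse(cos(table$psi * pi / 180) >= 0, "up", "down")
  }
  fids <- unique(table$filament_id)
  votes <- do.call(rbind, lapply(fids, function(f) {
    flags <- table$polarity_flag[table$filament_id == f]
    n_up <- sum(flags == "up")
    n <- length(flags)
    up <- n_up >= n / 2
    data.frame(filament_id = f,
               polarity = if (up) "up" else "down",
               confidence = max(n_up, n - n_up) / n,
               n_segments = n,
               singleton = n == 1L)
  }))
  if (apply) {
    for (i in seq_len(nrow(votes))) {
      f <- votes$filament_id[i]
      minority <- table$filament_id == f &
        table$polarity_flag != votes$polarity[i]
      if (any(minority) && !is.null(table$psi)) {
        table$psi[minority] <- (table$psi[minority] + 180) %% 360
        if (!is.null(table$rot))
          table$rot[minority] <- (-table$rot[minority]) %% 360
        if (!is.null(table$shift_axial))
          table$shift_axial[minority] <- -table$shift_axial[minority]
        table$polarity_flag[minority] <- votes$polarity[i]
      }
    }
  }
  list(votes = votes, table = table)
}
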