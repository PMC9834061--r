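#' Particle and segment metadata tables
#'
#' Particle tables are plain data.frames with one row per particle (or
#' filament segment). All positions are physical Angstrom; all angles are
#' intrinsic ZYZ Euler angles in degrees describing the rotation that takes
#' the reference into the particle. Mandatory columns:
#' `particle_id`, `center_x`, `center_y`, `center_z`,
#' `euler_phi`, `euler_theta`, `euler_psi`.
#' Optional columns used by the filament stages: `source_volume_id`,
#' `filament_id`, `arc_position`, `tangent_x/y/z`, `class_id`, `score`,
#' `polarity_flag`. Unknown columns round-trip untouched.
#'
#' @param df a data.frame to validate as a particle table.
#' @return the validated data.frame, invisibly.
#' @export
validate_particle_table <- function(df) {
  mandatory <- c("particle_id", "center_x", "center_y", "center_z",
                 "euler_phi", "euler_theta", "euler_psi")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("particle table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$particle_id))
    stop("particle_id values must be unique")
  ang <- as.matrix(df[, c("euler_phi", "euler_theta", "euler_psi")])
  if (nrow(df) && !all(is.finite(ang)))
    stop("euler angles must be finite")
  if ("arc_position" %in% names(df) && nrow(df)) {
    if (any(df$arc_position < -1e-9, na.rm = TRUE))
      stop("arc_position must be non-negative")
    if ("filament_id" %in% names(df)) {
      for (fid in unique(df$filament_id)) {
        a <- df$arc_position[df$filament_id == fid]
        a <- a[!is.na(a)]
        if (length(a) > 1 && any(diff(a) <= 0))
          stop("arc_position must be strictly increasing within filament ", fid)
      }
    }
  }
  invisible(df)
}

fmt_star_value <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) return("NA")
      s <- sprintf("%.15g", v)
      s
    }, character(1))
    out
  } else {
    as.character(x)
  }
}

#' Write a particle table (STAR or TSV)
#'
#' The on-disk dialect is chosen by extension: `.star` writes a single
#' `data_particles` block with a `loop_` whose labels are the column names
#' prefixed with `_`; anything else writes a tab-separated table with a
#' header line. Both dialects are lossless for numeric values to double
#' precision.
#'
#' @param table a validated particle table data.frame.
#' @param path output path (`.star` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(table, path) {
  validate_particle_table(table)
  if (grepl("\\.star$", path, ignore.case = TRUE)) {
    cols <- names(table)
    lines <- c(
      "# Angstrom coordinates; intrinsic ZYZ Euler angles (degrees),",
      "# rotation of the reference into the particle.",
      "",
      "data_particles", "", "loop_",
      sprintf("_%s #%d", cols, seq_along(cols))
    )
    if (nrow(table)) {
      body <- do.call(paste, c(lapply(table, fmt_star_value), sep = "\t"))
      lines <- c(lines, body)
    }
    writeLines(lines, path)
  } else {
    utils::write.table(
      data.frame(lapply(table, fmt_star_value), check.names = FALSE,
                 stringsAsFactors = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a particle table (STAR or TSV)
#'
#' @param path path written by [write_particle_table()] (or any STAR file
#'   with a single loop of per-particle labels).
#' @return a validated particle table data.frame.
#' @export
read_particle_table <- function(path) {
  if (!file.exists(path)) stop("particle table does not exist: ", path)
  if (grepl("\\.star$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines)]
    loop_at <- which(trimws(lines) == "loop_")
    if (!length(loop_at)) stop("malformed STAR file: no loop_ block in ", path)
    i <- loop_at[1] + 1
    cols <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      lbl <- sub("^\\s*_([^ #\t]+).*$", "\\1", lines[i])
      cols <- c(cols, lbl)
      i <- i + 1
    }
    body <- lines[seq(i, length.out = max(0, length(lines) - i + 1))]
    body <- body[nzchar(trimws(body))]
    if (length(body)) {
      df <- utils::read.table(text = body, sep = "\t", header = FALSE,
                              col.names = cols, stringsAsFactors = FALSE,
                              check.names = FALSE)
    } else {
      df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                          cols), check.names = FALSE)
    }
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  validate_particle_table(df)
  df
}
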