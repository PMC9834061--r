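#' Run configuration
#'
#' Bundles the acquisition and processing parameters shared by all stages.
#' Defaults follow the acquisition and processing settings of the in situ
#' filament workflow this package implements: 4.51 A unbinned pixels,
#' binning 4, a -60..+60 degree single-axis tilt range in 2 degree steps,
#' a 60 A low-pass on external alignment references, 32.13 A intersegment
#' distance, and three refinement iterations.
#'
#' @param pixel_size_unbinned unbinned pixel size in Angstrom.
#' @param binning integer binning factor (>= 1); the working voxel size is
#'   `pixel_size_unbinned * binning`.
#' @param tilt_min,tilt_max tilt range in degrees (`tilt_min < tilt_max`).
#' @param tilt_increment tilt step in degrees.
#' @param lowpass_reference low-pass cutoff (Angstrom) applied to external
#'   references before alignment; must exceed twice the working voxel size.
#' @param intersegment_distance filament segmentation spacing in Angstrom.
#' @param n_iterations number of filament-analysis iterations (>= 1).
#' @param rng_seed integer seed controlling all randomness in a run.
#' @param box_size segment/particle box size in voxels (even).
#' @return a `run_config` list.
#' @export
run_config <- function(pixel_size_unbinned = 4.51,
                       binning = 4L,
                       tilt_min = -60, tilt_max = 60,
                       tilt_increment = 2,
                       lowpass_reference = 60,
                       intersegment_distance = 32.13,
                       n_iterations = 3L,
                       rng_seed = 1L,
                       box_size = 64L) {
  cfg <- list(pixel_size_unbinned = pixel_size_unbinned,
              binning = as.integer(binning),
              tilt_min = tilt_min, tilt_max = tilt_max,
              tilt_increment = tilt_increment,
              lowpass_reference = lowpass_reference,
              intersegment_distance = intersegment_distance,
              n_iterations = as.integer(n_iterations),
              rng_seed = as.integer(rng_seed),
              box_size = as.integer(box_size))
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$binning < 1L) stop("binning must be >= 1")
  if (cfg$pixel_size_unbinned <= 0) stop("pixel size must be positive")
  if (!(cfg$tilt_min < cfg$tilt_max)) stop("tilt_min must be < tilt_max")
  vox <- cfg$pixel_size_unbinned * cfg$binning
  if (cfg$lowpass_reference <= 2 * vox)
    stop(sprintf("lowpass_reference (%.2f A) must exceed twice the binned pixel size (2 x %.2f A)",
                 cfg$lowpass_reference, vox))
  if (cfg$n_iterations < 1L) stop("n_iterations must be >= 1")
  if (cfg$intersegment_distance <= 0) stop("intersegment_distance must be positive")
  invisible(cfg)
}

#' Working voxel size of a configuration
#' @param cfg a [run_config()].
#' @return binned pixel size in Angstrom.
#' @export
config_voxel_size <- function(cfg) cfg$pixel_size_unbinned * cfg$binning

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @rdname run_config_io
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @param cfg a [run_config()].
#' @rdname run_config_io
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ---- machine-readable run record ------------------------------------------

run_record_env <- new.env(parent = emptyenv())
run_record_env$events <- list()

#' Append an event to the in-memory run record
#'
#' Every pipeline stage logs its name, parameters and RNG seed here; the
#' record can be serialized with [write_run_record()] to make a run fully
#' auditable.
#'
#' @param stage short stage name.
#' @param ... named parameters to record (must be JSON-serializable).
#' @return invisibly, the event list entry.
#' @export
log_run_event <- function(stage, ...) {
  ev <- list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
             params = list(...))
  run_record_env$events[[length(run_record_env$events) + 1L]] <- ev
  invisible(ev)
}

#' Retrieve or reset the run record
#' @return list of logged events.
#' @rdname run_record
#' @export
get_run_record <- function() run_record_env$events

#' @rdname run_record
#' @export
reset_run_record <- function() {
  run_record_env$events <- list()
  invisible(NULL)
}

#' @param path output JSON path.
#' @rdname run_record
#' @export
write_run_record <- function(path) {
  jsonlite::write_json(run_record_env$events, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
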