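#' Helical symmetry parameters
#'
#' Rise (Angstrom per subunit) and twist (degrees per subunit, negative =
#' left-handed) of a 1-start helix. The F-actin-like values refined for the
#' Lokiarchaeal cytoskeletal filament are rise 27.9 A, twist -167.7 deg;
#' the canonical F-actin textbook values (27.5 A, -166.7 deg) are used as
#' the external-reference prior.
#'
#' @param rise axial rise per subunit in Angstrom (> 0).
#' @param twist azimuthal twist per subunit in degrees, in (-180, 180].
#' @return a `helical_params` object.
#' @export
helical_params <- function(rise, twist) {
  if (!is.numeric(rise) || length(rise) != 1L || rise <= 0)
    stop("rise must be a single positive number (Angstrom)")
  if (!is.numeric(twist) || length(twist) != 1L || twist <= -180 || twist > 180)
    stop("twist must be a single number in (-180, 180] degrees")
  structure(list(rise = as.numeric(rise), twist = as.numeric(twist)),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("<helical_params> rise %.3f A/subunit, twist %.3f deg/subunit (%s-handed 1-start)\n",
              x$rise, x$twist, if (x$twist < 0) "left" else "right"))
  invisible(x)
}

#' @export
format.helical_params <- function(x, ...) {
  sprintf("rise=%.3f A, twist=%.3f deg", x$rise, x$twist)
}
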