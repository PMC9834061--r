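#' Read an MRC2014 density volume
#'
#' Reads modes 0 (int8), 1 (int16), 2 (float32) and 12 (float16 is not
#' supported and raises an error naming the mode). The voxel size is taken
#' from the header cell dimensions divided by the grid size; the physical
#' origin from the ORIGIN header words.
#'
#' @param path path to an `.mrc` file.
#' @return A [new_volume()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("MRC file does not exist: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    stop("malformed MRC file (header truncated, file size ", sz, " < 1024): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_dbl <- readBin(con, "numeric", n = 256, size = 4, endian = "little")

  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- hdr_dbl[11:13]
  nsymbt <- hdr_int[24]
  origin <- hdr_dbl[50:52]

  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5))
    stop("malformed MRC header: invalid grid dimensions nx/ny/nz = ",
         paste(c(nx, ny, nz), collapse = "x"))
  if (!mode %in% c(0L, 1L, 2L))
    stop("malformed MRC header: unsupported data mode ", mode,
         " (modes 0, 1 and 2 are supported)")
  if (is.na(nsymbt) || nsymbt < 0 || nsymbt > sz)
    stop("malformed MRC header: invalid extended-header size (nsymbt)")

  n <- as.double(nx) * ny * nz
  bytes_per <- c(`0` = 1L, `1` = 2L, `2` = 4L)[[as.character(mode)]]
  if (1024 + nsymbt + n * bytes_per > sz)
    stop("malformed MRC file: data section truncated (expected ",
         1024 + nsymbt + n * bytes_per, " bytes, file has ", sz, ")")

  seek(con, 1024 + nsymbt)
  data <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE,
                             endian = "little")),
    `1` = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    `2` = readBin(con, "numeric", n = n, size = 4, endian = "little"))
  dim(data) <- c(nx, ny, nz)

  if (any(!is.finite(data))) data[!is.finite(data)] <- 0
  if (mx <= 0 || my <= 0 || mz <= 0)
    stop("malformed MRC header: sampling grid mx/my/mz must be positive")
  vx <- cella[1] / mx
  if (!is.finite(vx) || vx <= 0) vx <- 1
  new_volume(data, voxel_size = vx, origin = origin)
}

#' Write an MRC2014 density volume
#'
#' Writes a mode-2 (float32) MRC2014 file. The cell dimensions are set to
#' grid size times voxel size, the ORIGIN words to the volume origin.
#'
#' @param volume a [new_volume()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot_volume(volume)
  d <- dim(volume$data)
  if (any(d < 1L) || length(volume$data) == 0L)
    stop("refusing to write a zero-size volume")
  con <- file(path, "wb")
  on.exit(close(con))

  wi <- function(pos, val) { seek(con, (pos - 1) * 4); writeBin(as.integer(val), con, size = 4, endian = "little") }
  wf <- function(pos, val) { seek(con, (pos - 1) * 4); writeBin(as.numeric(val), con, size = 4, endian = "little") }

  writeBin(raw(1024), con)
  wi(1, d[1]); wi(2, d[2]); wi(3, d[3])
  wi(4, 2L)                                  # mode 2 float32
  wi(5, 0L); wi(6, 0L); wi(7, 0L)            # nxstart
  wi(8, d[1]); wi(9, d[2]); wi(10, d[3])     # mx my mz
  wf(11, d[1] * volume$voxel_size)
  wf(12, d[2] * volume$voxel_size)
  wf(13, d[3] * volume$voxel_size)
  wf(14, 90); wf(15, 90); wf(16, 90)         # cell angles
  wi(17, 1L); wi(18, 2L); wi(19, 3L)         # axis order
  wf(20, min(volume$data)); wf(21, max(volume$data)); wf(22, mean(volume$data))
  wi(23, 1L)                                  # ispg: volume
  wi(24, 0L)                                  # no extended header
  wi(28, 20140L)                              # NVERSION
  wf(50, volume$origin[1]); wf(51, volume$origin[2]); wf(52, volume$origin[3])
  seek(con, 52 * 4)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(55, stats::sd(as.vector(volume$data)))

  seek(con, 1024)
  writeBin(as.numeric(volume$data), con, size = 4, endian = "little")
  invisible(path)
}
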