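# MRC2014 reader/writer, mode-2 (32-bit float), little-endian.
# Data layout: x fastest (column-major), matching R array indexing.
# Pixel size is carried in the cell dimensions (CELLA / MX etc.).
# ISPG = 1 marks a volume, 0 an image or particle stack.

#' Write an image, stack or volume as an MRC2014 file
#'
#' Writes mode-2 (float) MRC with the pixel size encoded in the header cell
#' parameters. Round trips through [read_mrc()] preserve the payload
#' bit-identically (float32 precision) and the pixel size.
#'
#' @param x `em_image`, `em_stack` or `em_volume`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_mrc <- function(x, path) {
  d <- dim(x$data)
  if (length(d) == 2L) d <- c(d, 1L)
  is_volume <- inherits(x, "em_volume")
  px <- x$pixel_size
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  dat <- as.single_safe(x$data)
  wi(d)                                   # NX NY NZ
  wi(2L)                                  # MODE 2 = float32
  wi(c(0L, 0L, 0L))                       # NXSTART..
  wi(d)                                   # MX MY MZ
  wf(d * px)                              # CELLA (A)
  wf(c(90, 90, 90))                       # CELLB
  wi(c(1L, 2L, 3L))                       # MAPC MAPR MAPS
  wf(c(min(dat), max(dat), mean(dat)))    # DMIN DMAX DMEAN
  wi(if (is_volume) 1L else 0L)           # ISPG
  wi(0L)                                  # NSYMBT
  wi(integer(25))                         # EXTRA
  wf(c(0, 0, 0))                          # ORIGIN
  writeBin(charToRaw("MAP "), con)        # MAP
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(dat))                             # RMS
  wi(0L)                                  # NLABL
  writeBin(raw(800), con)                 # labels
  writeBin(dat, con, size = 4, endian = "little")
  invisible(path)
}

# values representable in float32 (so round trips are bit-identical)
as.single_safe <- function(a) as.numeric(readBin(writeBin(
  as.numeric(a), raw(), size = 4, endian = "little"),
  "numeric", n = length(a), size = 4, endian = "little"))

#' Read an MRC2014 file
#'
#' Only mode-2 (float) files are supported. Returns an `em_volume` when the
#' header marks a volume (ISPG >= 1) or the file is cubic with NZ > 1, an
#' `em_image` for single sections, and an `em_stack` otherwise.
#'
#' @param path file path
#' @return `em_image`, `em_stack` or `em_volume`
#' @export
read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("not an MRC file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)                  # nxstart
  m <- ri(3)             # MX MY MZ
  cella <- rf(3)
  rf(3)                  # cellb
  ri(3)                  # mapc/mapr/maps
  rf(3)                  # dmin/dmax/dmean
  ispg <- ri(1)
  nsymbt <- ri(1)
  seek(con, 208)
  map_id <- readChar(con, 4, useBytes = TRUE)
  if (any(d <= 0) || any(d > 1e5)) stop("inconsistent MRC header dims")
  if (!identical(map_id, "MAP ")) stop("not an MRC2014 file: ", path)
  if (mode != 2) stop("unsupported MRC mode (only mode 2 float): ", mode)
  n <- prod(d)
  if (sz < 1024 + nsymbt + 4 * n) stop("truncated MRC file: ", path)
  seek(con, 1024 + nsymbt)
  dat <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  px <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else 1
  a <- array(dat, dim = d)
  if (d[3] == 1L) {
    em_image(a[, , 1], px)
  } else if (ispg >= 1L && d[1] == d[2] && d[2] == d[3]) {
    em_volume(a, px)
  } else {
    em_stack(a, px)
  }
}
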