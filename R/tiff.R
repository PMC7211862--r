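#' @useDynLib nmjmetrics, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Minimal baseline-TIFF support (uncompressed grayscale, little-endian,
# multi-page) with an ImageJ-style hyperstack ImageDescription carrying the
# channel/slice layout and the spatial unit. This is deliberately a small
# subset of TIFF: enough to round-trip the package's own fixtures and to read
# plain uncompressed exports from Fiji/tifffile. Calibration is stored in the
# X/YResolution tags as pixels-per-micron.

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)

#' Write a grayscale multi-page TIFF
#'
#' Pages are written uncompressed (baseline TIFF, little-endian), one strip
#' per page, 8- or 16-bit unsigned. Channel/slice structure is recorded in an
#' ImageJ-style `ImageDescription` (`images=`, `channels=`, `slices=`,
#' `unit=micron`) with channels interleaved fastest, so files written here are
#' readable by Fiji and by Python's tifffile.
#'
#' @param pages list of numeric matrices (all the same size), page order
#'   channel-fastest when `channels > 1`.
#' @param path output file path.
#' @param calibration_um_per_px pixel size in micrometres, or `NA` to omit
#'   calibration metadata.
#' @param channels,slices hyperstack layout; `channels * slices` must equal
#'   `length(pages)`.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, calibration_um_per_px = NA_real_,
                       channels = 1L, slices = length(pages) %/% channels,
                       bits = 8L) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, bits %in% c(8L, 16L),
            channels * slices == length(pages))
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  for (p in pages) stopifnot(nrow(p) == h, ncol(p) == w, all(p >= 0))
  maxval <- 2^bits - 1
  n <- length(pages)

  desc <- sprintf(
    "ImageJ=1.52i\nimages=%d\nchannels=%d\nslices=%d\nunit=micron\n",
    n, channels, slices)
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  bytes_pp <- bits / 8L
  strip_len <- h * w * bytes_pp
  has_cal <- is.finite(calibration_um_per_px) && calibration_um_per_px > 0

  # layout: header | page strips | description | shared rational | IFDs
  off_strip0 <- 8L
  off_desc <- off_strip0 + n * strip_len
  off_rat <- off_desc + length(desc_raw)
  off_ifd0 <- off_rat + 8L
  n_entries1 <- if (has_cal) 13L else 10L    # first IFD carries Description
  n_entriesk <- n_entries1 - 1L
  ifd_size1 <- 2L + n_entries1 * 12L + 4L
  ifd_sizek <- 2L + n_entriesk * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(x, size) writeBin(as.integer(x), con, size = size,
                                    endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  wle(42L, 2L)
  wle(off_ifd0, 4L)
  # pixel strips, row-major
  for (p in pages) {
    v <- as.integer(round(pmin(pmax(t(p), 0), maxval)))
    wle(v, bytes_pp)
  }
  writeBin(desc_raw, con)
  # shared X/Y resolution rational: pixels per micron = 1/cal
  if (has_cal) {
    denom <- 1e6L
    numer <- round(1e6 / calibration_um_per_px)
    wle(numer, 4L); wle(denom, 4L)
  } else {
    wle(0L, 4L); wle(0L, 4L)
  }

  entry <- function(tag, type, count, value) {
    wle(tag, 2L); wle(type, 2L); wle(count, 4L)
    if (type == .tiff_types[["SHORT"]] && count == 1L) {
      wle(value, 2L); wle(0L, 2L)
    } else wle(value, 4L)
  }
  for (k in seq_len(n)) {
    wle(if (k == 1L) n_entries1 else n_entriesk, 2L)
    entry(256L, 4L, 1L, w)
    entry(257L, 4L, 1L, h)
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)       # no compression
    entry(262L, 3L, 1L, 1L)       # black-is-zero
    if (k == 1L) entry(270L, 2L, length(desc_raw), off_desc)
    entry(273L, 4L, 1L, off_strip0 + (k - 1L) * strip_len)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, h)
    entry(279L, 4L, 1L, strip_len)
    if (has_cal) {
      entry(282L, 5L, 1L, off_rat)
      entry(283L, 5L, 1L, off_rat)
      entry(296L, 3L, 1L, 1L)     # unit carried by the description
    }
    nxt <- if (k < n) off_ifd0 + ifd_size1 + (k - 1L) * ifd_sizek else 0L
    wle(nxt, 4L)
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF
#'
#' Supports uncompressed baseline grayscale TIFF (8/16-bit, either byte
#' order, strip-organized). Returns the pages plus whatever layout and
#' calibration metadata could be recovered.
#'
#' @param path TIFF file path.
#' @return list with `pages` (list of numeric matrices), `channels`, `slices`
#'   and `calibration_um_per_px` (`NA` when the file carries none).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: no such file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path)
  rint <- function(off, size, n = 1L) {
    # sizes 1/2 read unsigned; 4-byte values are fine signed (files < 2 GiB)
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size > 2L)
  }
  if (rint(2L, 2L) != 42L) stop("not a TIFF file (bad magic): ", path)

  pages <- list()
  desc <- ""
  xres <- NA_real_
  res_unit <- 1L
  ifd_off <- rint(4L, 4L)
  while (ifd_off != 0L) {
    ne <- rint(ifd_off, 2L)
    tags <- list()
    for (e in seq_len(ne)) {
      eo <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rint(eo, 2L); type <- rint(eo + 2L, 2L); count <- rint(eo + 4L, 4L)
      tsize <- c(1L, 1L, 2L, 4L, 8L)[type]
      inline <- tsize * count <= 4L
      voff <- if (inline) eo + 8L else rint(eo + 8L, 4L)
      val <- switch(as.character(type),
        "2" = rawToChar(raw[(voff + 1L):(voff + count)] [
          raw[(voff + 1L):(voff + count)] != as.raw(0L)]),
        "5" = {
          nu <- rint(voff, 4L, n = 2L * count)
          nu[seq(1L, 2L * count, 2L)] / nu[seq(2L, 2L * count, 2L)]
        },
        rint(voff, tsize, n = count))
      tags[[as.character(tag)]] <- val
    }
    need <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF missing required tag ", t)
        default
      } else v
    }
    w <- need(256L); h <- need(257L)
    bits <- need(258L, 8L)[1L]
    comp <- need(259L, 1L)
    if (comp != 1L) stop("unsupported TIFF compression (", comp,
                         "); re-save uncompressed: ", path)
    spp <- need(277L, 1L)
    if (spp != 1L) stop("unsupported TIFF: samples-per-pixel ", spp,
                        " (expected 1 grayscale sample; split channels ",
                        "into pages): ", path)
    offs <- need(273L); cnts <- need(279L, rep(w * h * bits / 8L,
                                               length(offs)))
    bpp <- bits / 8L
    vals <- integer(0)
    for (s in seq_along(offs)) {
      nv <- cnts[s] / bpp
      vals <- c(vals, rint(offs[s], bpp, n = nv))
    }
    pages[[length(pages) + 1L]] <- matrix(vals[seq_len(w * h)], nrow = h,
                                          byrow = TRUE)
    if (!is.null(tags[["270"]]) && nchar(desc) == 0L) desc <- tags[["270"]]
    if (!is.null(tags[["282"]])) xres <- tags[["282"]][1L]
    if (!is.null(tags[["296"]])) res_unit <- tags[["296"]][1L]
    ifd_off <- rint(ifd_off + 2L + ne * 12L, 4L)
  }

  grab <- function(key) {
    m <- regmatches(desc, regexec(paste0(key, "=([^\n]+)"), desc))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
  }
  channels <- suppressWarnings(as.integer(grab("channels")))
  slices <- suppressWarnings(as.integer(grab("slices")))
  unit <- grab("unit")
  if (is.na(channels)) channels <- 1L
  if (is.na(slices)) slices <- length(pages) %/% channels

  cal <- NA_real_
  if (is.finite(xres) && xres > 0) {
    if (!is.na(unit) && unit %in% c("micron", "um", "µm", "microns")) {
      cal <- 1 / xres
    } else if (res_unit == 2L) {        # inch
      cal <- 25400 / xres
    } else if (res_unit == 3L) {        # cm
      cal <- 10000 / xres
    }
  }
  list(pages = pages, channels = channels, slices = slices,
       calibration_um_per_px = cal)
}
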