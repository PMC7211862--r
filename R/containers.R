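# S3 containers shared across the pipeline. Everything is a plain matrix plus
# a micrometre-per-pixel calibration; constructors validate invariants once so
# downstream code can assume them.

#' Calibrated 2-D intensity image
#'
#' @param pixels numeric matrix of non-negative intensities (row 1 = top).
#' @param calibration_um_per_px positive pixel size in micrometres.
#' @param channel_role `"nerve"` or `"achr"`.
#' @return an object of class `nmj_image`.
#' @export
nmj_image <- function(pixels, calibration_um_per_px,
                      channel_role = c("achr", "nerve")) {
  channel_role <- match.arg(channel_role)
  stopifnot(is.matrix(pixels), all(pixels >= 0))
  .check_cal(calibration_um_per_px)
  structure(list(pixels = pixels,
                 calibration_um_per_px = calibration_um_per_px,
                 channel_role = channel_role),
            class = "nmj_image")
}

#' Calibrated multi-channel z-stack
#'
#' @param voxels 4-D array indexed `[channel, slice, row, col]` (a 3-D
#'   `[slice, row, col]` array or 2-D image is promoted to one channel /
#'   one slice).
#' @param calibration_um_per_px positive pixel size in micrometres.
#' @param channel_roles character vector naming each channel's role; must
#'   contain `"nerve"` and `"achr"` exactly once each for pipeline use (a
#'   single-channel stack may carry just one of them).
#' @return an object of class `nmj_zstack`.
#' @export
nmj_zstack <- function(voxels, calibration_um_per_px, channel_roles) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, c(1L, 1L, dim(voxels)))
  } else if (length(dim(voxels)) == 3L) {
    voxels <- array(voxels, c(1L, dim(voxels)))
  }
  stopifnot(length(dim(voxels)) == 4L, all(voxels >= 0), dim(voxels)[2] >= 1L)
  .check_cal(calibration_um_per_px)
  stopifnot(length(channel_roles) == dim(voxels)[1],
            !anyDuplicated(channel_roles))
  structure(list(voxels = voxels,
                 calibration_um_per_px = calibration_um_per_px,
                 channel_roles = channel_roles),
            class = "nmj_zstack")
}

#' Binary foreground mask
#'
#' @param pixels logical matrix (or 0/1 numeric).
#' @param calibration_um_per_px positive pixel size in micrometres.
#' @return an object of class `nmj_mask`.
#' @export
nmj_mask <- function(pixels, calibration_um_per_px) {
  if (!is.logical(pixels)) {
    stopifnot(all(pixels %in% c(0, 1)))
    pixels <- matrix(as.logical(pixels), nrow(pixels), ncol(pixels))
  }
  stopifnot(is.matrix(pixels))
  .check_cal(calibration_um_per_px)
  structure(list(pixels = pixels,
                 calibration_um_per_px = calibration_um_per_px),
            class = "nmj_mask")
}

#' Integer-labeled particle image
#'
#' Labels are consecutive `1..K`; 0 is background.
#'
#' @param labels non-negative integer matrix.
#' @param calibration_um_per_px positive pixel size in micrometres.
#' @return an object of class `nmj_labels`.
#' @export
nmj_labels <- function(labels, calibration_um_per_px) {
  stopifnot(is.matrix(labels), all(labels >= 0))
  u <- sort(unique(labels[labels > 0]))
  if (length(u) && !identical(as.integer(u), seq_along(u)))
    stop("labels must be consecutive 1..K")
  .check_cal(calibration_um_per_px)
  structure(list(labels = labels,
                 calibration_um_per_px = calibration_um_per_px),
            class = "nmj_labels")
}

.check_cal <- function(cal) {
  if (!is.numeric(cal) || length(cal) != 1L || !is.finite(cal) || cal <= 0)
    stop("calibration_um_per_px must be a single positive number")
  invisible(cal)
}

#' @export
print.nmj_image <- function(x, ...) {
  cat(sprintf("<nmj_image %s: %d x %d px, %.4g um/px>\n", x$channel_role,
              nrow(x$pixels), ncol(x$pixels), x$calibration_um_per_px))
  invisible(x)
}

#' @export
print.nmj_zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<nmj_zstack: %d channel(s) [%s], %d slice(s), %d x %d px, %.4g um/px>\n",
              d[1], paste(x$channel_roles, collapse = ","), d[2], d[3], d[4],
              x$calibration_um_per_px))
  invisible(x)
}

#' @export
print.nmj_mask <- function(x, ...) {
  cat(sprintf("<nmj_mask: %d x %d px, %d foreground px, %.4g um/px>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              x$calibration_um_per_px))
  invisible(x)
}

#' @export
print.nmj_labels <- function(x, ...) {
  cat(sprintf("<nmj_labels: %d x %d px, %d particle(s), %.4g um/px>\n",
              nrow(x$labels), ncol(x$labels), max(x$labels),
              x$calibration_um_per_px))
  invisible(x)
}

.mask_int <- function(mask) {
  # 0/1 integer matrix view for the C++ kernels
  m <- mask
  if (inherits(mask, "nmj_mask")) m <- mask$pixels
  matrix(as.integer(m), nrow(m), ncol(m))
}
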