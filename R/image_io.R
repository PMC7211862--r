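# Reading calibrated stacks, projecting channels, writing the results table.

#' Load a two-channel (or single-channel) z-stack from TIFF
#'
#' Only TIFF/OME-TIFF is supported; proprietary microscope formats (.lsm,
#' .nd2, ...) must be converted first. Calibration precedence is strict:
#' the file's resolution metadata wins, then `calibration_um_per_px`; if
#' neither is available the call errors, because every downstream metric is
#' in micrometres and a silently assumed scale would corrupt them.
#'
#' @param path TIFF file.
#' @param channel_map named integer vector mapping channel roles to 1-based
#'   channel indices, e.g. `c(nerve = 1, achr = 2)`.
#' @param calibration_um_per_px optional fallback pixel size (micrometres)
#'   used when the file has no resolution metadata.
#' @return an [nmj_zstack] whose channels are ordered as in `channel_map`.
#' @export
load_stack <- function(path, channel_map = c(nerve = 1L, achr = 2L),
                       calibration_um_per_px = NULL) {
  tf <- read_tiff(path)
  n_chan <- tf$channels
  n_slice <- tf$slices
  if (n_chan * n_slice != length(tf$pages)) {
    # un-annotated multi-page file: treat pages as slices of one channel
    n_chan <- 1L
    n_slice <- length(tf$pages)
  }
  if (any(channel_map < 1L) || any(channel_map > n_chan))
    stop("channel_map index out of bounds for ", path, " (", n_chan,
         " channel(s) present)")
  if (is.null(names(channel_map)) || anyDuplicated(names(channel_map)))
    stop("channel_map must have unique role names")

  cal <- tf$calibration_um_per_px
  if (!is.finite(cal) || cal <= 0) {
    if (is.null(calibration_um_per_px))
      stop("no spatial calibration for image '", path,
           "': none in TIFF metadata and no config override supplied")
    .check_cal(calibration_um_per_px)
    cal <- calibration_um_per_px
  }

  h <- nrow(tf$pages[[1L]]); w <- ncol(tf$pages[[1L]])
  vox <- array(0, c(length(channel_map), n_slice, h, w))
  for (k in seq_along(channel_map)) {
    ci <- channel_map[[k]]
    for (z in seq_len(n_slice)) {
      # ImageJ hyperstack page order: channel varies fastest
      vox[k, z, , ] <- tf$pages[[(z - 1L) * n_chan + ci]]
    }
  }
  nmj_zstack(vox, cal, names(channel_map))
}

#' Maximum-intensity projection of one channel
#'
#' @param stack an [nmj_zstack].
#' @param role channel role to project (`"nerve"` or `"achr"`).
#' @return an [nmj_image]; each output pixel is the maximum of that channel
#'   over slices, so a single-slice stack projects to itself.
#' @export
max_project <- function(stack, role) {
  stopifnot(inherits(stack, "nmj_zstack"))
  k <- match(role, stack$channel_roles)
  if (is.na(k)) stop("channel role '", role, "' not present in stack")
  d <- dim(stack$voxels)
  px <- apply(array(stack$voxels[k, , , ], d[2:4]), c(2L, 3L), max)
  nmj_image(px, stack$calibration_um_per_px, role)
}

#' Column order of the 19-variable results table
#'
#' The canonical variable list in its tabulated order: 7 pre-synaptic, 11
#' post-synaptic, 1 associated-nerve variable.
#' @return character vector of 19 column names.
#' @export
nmj_variable_names <- function() {
  c("nerve_terminal_area_um2", "nerve_terminal_perimeter_um",
    "n_terminal_branches", "n_branch_points", "total_branch_length_um",
    "average_branch_length_um", "complexity",
    "achr_area_um2", "achr_perimeter_um", "endplate_area_um2",
    "endplate_perimeter_um", "endplate_diameter_um", "n_achr_clusters",
    "average_cluster_area_um2", "fragmentation", "compactness_pct",
    "overlap_pct", "synaptic_contact_area_um2",
    "axon_diameter_um")
}

.provenance_names <- function() {
  c("image_id", "image_width_px", "image_height_px", "calibration_um_per_px",
    "threshold_method", "threshold_nerve", "threshold_achr", "qc_flags")
}

#' Convert analysis records to the results data frame
#'
#' @param records a single `nmj_record` (from [analyze_image]) or a list of
#'   them.
#' @return data.frame with one row per NMJ: the 19 metric columns in
#'   canonical order followed by provenance columns.
#' @export
records_to_table <- function(records) {
  if (inherits(records, "nmj_record")) records <- list(records)
  stopifnot(length(records) >= 1L)
  cols <- c(nmj_variable_names(), .provenance_names())
  rows <- lapply(records, function(r) {
    stopifnot(inherits(r, "nmj_record"))
    v <- r[cols]
    v$qc_flags <- paste(r$qc_flags, collapse = ";")
    as.data.frame(v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the curated results CSV
#'
#' One row per NMJ, the 19 morphometric variables in canonical order plus
#' image size, calibration, threshold selection and QC flags. Missing values
#' (e.g. cluster counts under aberrant segmentation) are written as empty
#' cells. RFC-4180, UTF-8, "." decimal separator.
#'
#' @param records list of `nmj_record` objects (or one record).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  tab <- records_to_table(records)
  utils::write.csv(tab, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
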