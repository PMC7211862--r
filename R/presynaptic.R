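# Axon handling: the retained manual inputs (diameter line, erase region)
# supplied as pixel coordinates, applied to the nerve mask.

#' Axon manual input
#'
#' @param line_endpoints 2 x 2 numeric matrix, rows = the two endpoints of
#'   the diameter line, columns = (row, col) pixel coordinates.
#' @param erase_region optional polygon (n >= 3 rows of (row, col) vertices)
#'   marking the axon region to erase from the nerve mask.
#' @return an object of class `nmj_axon`.
#' @export
axon_input <- function(line_endpoints = NULL, erase_region = NULL) {
  if (!is.null(line_endpoints)) {
    line_endpoints <- as.matrix(line_endpoints)
    stopifnot(nrow(line_endpoints) == 2L, ncol(line_endpoints) == 2L)
    if (all(line_endpoints[1, ] == line_endpoints[2, ]))
      stop("axon diameter line endpoints must be distinct")
  }
  if (!is.null(erase_region)) {
    erase_region <- as.matrix(erase_region)
    stopifnot(nrow(erase_region) >= 3L, ncol(erase_region) == 2L)
  }
  structure(list(line_endpoints = line_endpoints,
                 erase_region = erase_region), class = "nmj_axon")
}

#' Axon diameter from the manual line
#'
#' Euclidean length of the user-drawn line across the axon, in micrometres.
#'
#' @param axon an [axon_input] with `line_endpoints` set.
#' @param calibration_um_per_px pixel size.
#' @return diameter in micrometres.
#' @export
axon_diameter <- function(axon, calibration_um_per_px) {
  stopifnot(inherits(axon, "nmj_axon"))
  if (is.null(axon$line_endpoints))
    stop("axon_diameter: no diameter line supplied")
  .check_cal(calibration_um_per_px)
  d <- axon$line_endpoints[1, ] - axon$line_endpoints[2, ]
  sqrt(sum(d^2)) * calibration_um_per_px
}

#' Erase the axon region from the nerve mask
#'
#' Sets foreground pixels whose centers fall inside the erase polygon
#' (even-odd rule) to background; a no-op when the axon input carries no
#' erase region.
#'
#' @param nerve_mask [nmj_mask].
#' @param axon [axon_input].
#' @return the erased [nmj_mask].
#' @export
erase_axon <- function(nerve_mask, axon) {
  stopifnot(inherits(nerve_mask, "nmj_mask"), inherits(axon, "nmj_axon"))
  if (is.null(axon$erase_region)) return(nerve_mask)
  poly <- axon$erase_region
  if (any(poly[, 1] < 0) || any(poly[, 1] > nrow(nerve_mask$pixels) + 1) ||
      any(poly[, 2] < 0) || any(poly[, 2] > ncol(nerve_mask$pixels) + 1))
    stop("erase region extends outside the image bounds")
  inside <- .polygon_mask(poly, nrow(nerve_mask$pixels),
                          ncol(nerve_mask$pixels))
  nmj_mask(nerve_mask$pixels & !inside, nerve_mask$calibration_um_per_px)
}

# Even-odd scanline polygon rasterization at pixel centers; vertices are
# (row, col) continuous coordinates.
.polygon_mask <- function(poly, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  vr <- poly[, 1]; vc <- poly[, 2]
  n <- length(vr)
  for (r in seq_len(nr)) {
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((vr[i] <= r && vr[j] > r) || (vr[j] <= r && vr[i] > r)) {
        xs <- c(xs, vc[i] + (r - vr[i]) / (vr[j] - vr[i]) * (vc[j] - vc[i]))
      }
      j <- i
    }
    if (length(xs)) {
      xs <- sort(xs)
      for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        cols <- which(seq_len(nc) >= xs[k] & seq_len(nc) <= xs[k + 1L])
        out[r, cols] <- TRUE
      }
    }
  }
  out
}

#' Full pre-synaptic measurement of a nerve-terminal mask
#'
#' Area/perimeter of the (axon-erased) terminal, skeleton branch statistics
#' and the composite complexity score.
#'
#' @param nerve_mask [nmj_mask] of the nerve terminal (after axon erase).
#' @param prune_spurs_px spur suppression for branch counting (see
#'   [classify_skeleton]).
#' @return list of the 6 skeleton/region variables plus `complexity`.
#' @export
measure_nerve_terminal <- function(nerve_mask, prune_spurs_px = 2L) {
  mr <- measure_region(nerve_mask)
  skel <- skeletonize(nerve_mask)
  cls <- classify_skeleton(skel, prune_spurs_px = prune_spurs_px)
  len <- branch_lengths(skel, prune_spurs_px = prune_spurs_px)
  list(nerve_terminal_area_um2 = unname(mr["area_um2"]),
       nerve_terminal_perimeter_um = unname(mr["perimeter_um"]),
       n_terminal_branches = cls$n_terminal_branches,
       n_branch_points = cls$n_branch_points,
       total_branch_length_um = unname(len["total_um"]),
       average_branch_length_um = unname(len["average_um"]),
       complexity = complexity(cls$n_terminal_branches, cls$n_branch_points,
                               unname(len["total_um"])))
}
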