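# Post-synaptic measures: AChR clusters (with the fill-holes enclosure
# rule), endplate footprint measures, and the derived fractions.

#' Count AChR clusters within the endplate footprint
#'
#' Reproduces the automated counting recipe: each watershed particle is
#' hole-filled and overlaid on the endplate footprint; a particle lying
#' entirely inside a hole of another is thereby absorbed into its host (one
#' cluster, not two), and particles lying outside the footprint (adjacent
#' endplates, background debris) are excluded. This count can only ever be
#' less than or equal to the raw watershed particle count.
#'
#' @param achr_labels [nmj_labels] from [watershed_split] of `achr_mask`.
#' @param achr_mask [nmj_mask] the AChR mask the labels were derived from.
#' @param footprint [nmj_mask] endplate footprint (superset of `achr_mask`).
#' @param qc optional `nmj_segqc` from [check_segmentation]; when aberrant,
#'   all cluster fields are returned missing.
#' @param within `"centroid"` (default: a particle counts when its centroid
#'   pixel lies in the footprint) or `"subset"` (all its pixels must).
#' @return list (`nmj_clusterstats`): `n_clusters`,
#'   `average_cluster_area_um2` (AChR area / n), `fragmentation`
#'   (`1 - 1/n`), all `NA` under aberrant segmentation or when no cluster
#'   lies in the footprint.
#' @export
count_clusters <- function(achr_labels, achr_mask, footprint, qc = NULL,
                           within = c("centroid", "subset")) {
  stopifnot(inherits(achr_labels, "nmj_labels"), inherits(achr_mask, "nmj_mask"),
            inherits(footprint, "nmj_mask"))
  within <- match.arg(within)
  missing_stats <- structure(list(n_clusters = NA_integer_,
                                  average_cluster_area_um2 = NA_real_,
                                  fragmentation = NA_real_),
                             class = "nmj_clusterstats")
  if (!is.null(qc) && isTRUE(qc$aberrant)) return(missing_stats)

  lb <- achr_labels$labels
  k <- max(lb)
  if (k == 0L) return(missing_stats)
  nr <- nrow(lb); nc <- ncol(lb)
  cal <- achr_labels$calibration_um_per_px

  # fill holes particle-by-particle; any particle fully inside another's
  # hole region is absorbed
  hole_map <- matrix(FALSE, nr, nc)
  for (i in seq_len(k)) {
    part <- lb == i
    filled <- fill_holes(nmj_mask(part, cal))$pixels
    hole_map <- hole_map | (filled & !part)
  }
  absorbed <- logical(k)
  for (j in seq_len(k)) {
    pj <- lb == j
    absorbed[j] <- all(hole_map[pj])
  }

  # footprint membership
  keep <- logical(k)
  for (j in seq_len(k)) {
    if (absorbed[j]) next
    idx <- which(lb == j)
    if (within == "subset") {
      keep[j] <- all(footprint$pixels[idx])
    } else {
      ri <- round(mean((idx - 1L) %% nr + 1L))
      ci <- round(mean((idx - 1L) %/% nr + 1L))
      keep[j] <- footprint$pixels[ri, ci]
    }
  }
  n <- sum(keep)
  if (n == 0L) return(missing_stats)
  achr_area <- sum(achr_mask$pixels) * cal^2
  structure(list(n_clusters = as.integer(n),
                 average_cluster_area_um2 = achr_area / n,
                 fragmentation = 1 - 1 / n),
            class = "nmj_clusterstats")
}

#' Endplate area, perimeter and Feret diameter
#'
#' @param footprint [nmj_mask] from [build_footprint].
#' @return named numeric vector `c(area_um2, perimeter_um, diameter_um)`;
#'   the diameter is the maximum caliper ([feret_diameter]).
#' @export
endplate_measures <- function(footprint) {
  mr <- measure_region(footprint)
  c(mr, diameter_um = unname(feret_diameter(footprint)))
}

#' Compactness of the endplate
#'
#' AChR-stained area as a percentage of the endplate (footprint) area; in
#' (0, 100] whenever the footprint contains the AChR mask.
#'
#' @param achr_area_um2,endplate_area_um2 the two areas in um^2.
#' @return percentage.
#' @export
compactness <- function(achr_area_um2, endplate_area_um2) {
  if (!is.finite(achr_area_um2) || achr_area_um2 <= 0)
    stop("compactness: AChR area must be positive (no receptor signal?)")
  if (!is.finite(endplate_area_um2) || endplate_area_um2 <= 0)
    stop("compactness: endplate area must be positive")
  achr_area_um2 / endplate_area_um2 * 100
}

#' Synaptic contact area and overlap
#'
#' Contact is the area of the pixelwise intersection of nerve-terminal and
#' AChR masks; overlap normalizes it by the AChR area (in percent).
#'
#' @param nerve_mask,achr_mask [nmj_mask]s of identical shape and
#'   calibration.
#' @return named numeric vector `c(contact_area_um2, overlap_pct)`.
#' @export
synaptic_contact <- function(nerve_mask, achr_mask) {
  stopifnot(inherits(nerve_mask, "nmj_mask"), inherits(achr_mask, "nmj_mask"),
            identical(dim(nerve_mask$pixels), dim(achr_mask$pixels)),
            isTRUE(all.equal(nerve_mask$calibration_um_per_px,
                             achr_mask$calibration_um_per_px)))
  cal2 <- achr_mask$calibration_um_per_px^2
  contact <- sum(nerve_mask$pixels & achr_mask$pixels) * cal2
  achr <- sum(achr_mask$pixels) * cal2
  overlap <- if (achr > 0) contact / achr * 100 else NA_real_
  c(contact_area_um2 = contact, overlap_pct = overlap)
}
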