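# Calibrated geometry on binary masks: area, traced perimeter, Feret
# (maximum caliper) diameter.

#' Area and perimeter of a binary mask
#'
#' Area is the foreground pixel count times the squared calibration.
#' Perimeter is the summed chain-code length of the traced contours of all
#' particles (outer contours plus the contours of any enclosed holes),
#' tracing through boundary-pixel centers with steps of 1 (orthogonal) and
#' sqrt(2) (diagonal); a 10 x 10 px square therefore measures 36 px. Isolated
#' single-pixel particles fall back to the unit-square boundary (4 px).
#'
#' @param mask non-empty [nmj_mask].
#' @return named numeric vector `c(area_um2, perimeter_um)`.
#' @export
measure_region <- function(mask) {
  stopifnot(inherits(mask, "nmj_mask"))
  px <- mask$pixels
  if (!any(px)) stop("measure_region: empty mask")
  cal <- mask$calibration_um_per_px
  area <- sum(px) * cal^2
  per_px <- .total_contour_length(px)
  # enclosed holes contribute their own traced contour
  bg <- !px
  labbg <- cpp_label(matrix(as.integer(bg), nrow(bg), ncol(bg)), 4L)
  border <- unique(c(labbg[1, ], labbg[nrow(bg), ], labbg[, 1],
                     labbg[, ncol(bg)]))
  holes <- setdiff(unique(labbg[labbg > 0]), border[border > 0])
  for (h in holes) per_px <- per_px + .total_contour_length(labbg == h)
  c(area_um2 = area, perimeter_um = per_px * cal)
}

# Sum of outer-contour chain lengths over all 8-connected components.
.total_contour_length <- function(px) {
  lab <- cpp_label(matrix(as.integer(px), nrow(px), ncol(px)), 8L)
  total <- 0
  for (k in seq_len(max(lab))) total <- total + .trace_one(lab == k)
  total
}

# Moore-neighbor boundary trace of a single 8-connected component; returns
# the closed chain length through boundary-pixel centers.
.trace_one <- function(px) {
  idx <- which(px)
  if (length(idx) == 1L) return(4)     # unit-square fallback
  nr <- nrow(px)
  ri <- (idx - 1L) %% nr + 1L
  ci <- (idx - 1L) %/% nr + 1L
  r0 <- min(ri)
  c0 <- min(ci[ri == r0])              # topmost-leftmost start pixel
  # clockwise directions from north
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  wt <- ifelse(seq_len(8L) %% 2L == 1L, 1, sqrt(2))
  at <- function(r, c) r >= 1L && r <= nrow(px) && c >= 1L &&
    c <= ncol(px) && px[r, c]

  cur_r <- r0; cur_c <- c0
  dir_b <- 1L                          # backtrack points north (background)
  total <- 0
  first_move <- NULL
  steps <- 0L
  max_steps <- 4L * length(idx) + 8L
  repeat {
    moved <- FALSE
    for (k in 1:8) {
      d <- ((dir_b - 1L + k) %% 8L) + 1L
      qr <- cur_r + dr[d]; qc <- cur_c + dc[d]
      if (at(qr, qc)) {
        move <- c(cur_r, cur_c, qr, qc)
        if (is.null(first_move)) {
          first_move <- move
        } else if (identical(move, first_move)) {
          return(total)
        }
        total <- total + wt[d]
        # new backtrack: the neighbour just before the hit, relative to q
        pr <- cur_r + dr[((d - 2L) %% 8L) + 1L]
        pc <- cur_c + dc[((d - 2L) %% 8L) + 1L]
        dir_b <- which(dr == (pr - qr) & dc == (pc - qc))
        cur_r <- qr; cur_c <- qc
        moved <- TRUE
        break
      }
    }
    if (!moved) return(4)              # no neighbours: isolated pixel
    steps <- steps + 1L
    if (steps > max_steps) return(total)
  }
}

#' Feret (maximum caliper) diameter of a mask
#'
#' Maximum point-to-point distance over the convex hull of the foreground
#' pixel corner coordinates (unit-square pixel model, matching ImageJ's
#' Feret on pixel selections): a single pixel measures sqrt(2), a 1 x 10 px
#' line sqrt(101).
#'
#' @param mask non-empty [nmj_mask].
#' @return diameter in micrometres.
#' @export
feret_diameter <- function(mask) {
  stopifnot(inherits(mask, "nmj_mask"))
  px <- mask$pixels
  if (!any(px)) stop("feret_diameter: empty mask")
  idx <- which(px)
  nr <- nrow(px)
  ri <- (idx - 1L) %% nr + 1L
  ci <- (idx - 1L) %/% nr + 1L
  pts <- cbind(r = c(ri - 0.5, ri - 0.5, ri + 0.5, ri + 0.5),
               c = c(ci - 0.5, ci + 0.5, ci - 0.5, ci + 0.5))
  h <- grDevices::chull(pts[, "c"], pts[, "r"])
  hp <- pts[h, , drop = FALSE]
  d2 <- outer(hp[, "r"], hp[, "r"], "-")^2 + outer(hp[, "c"], hp[, "c"], "-")^2
  sqrt(max(d2)) * mask$calibration_um_per_px
}
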