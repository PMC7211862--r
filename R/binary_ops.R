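# Thresholding, hole filling, watershed particle splitting, endplate
# footprint construction and segmentation QC. Conventions: foreground is
# intensity >= the lower threshold; particles use 8-connectivity, background
# holes 4-connectivity (the standard digital-topology duality).

#' Threshold an intensity image to a binary mask
#'
#' @param image an [nmj_image].
#' @param method `"manual"` (requires `manual_value`) or `"otsu"`.
#' @param manual_value lower threshold; pixels with intensity `>=` it become
#'   foreground.
#' @return list with `mask` ([nmj_mask]), `record` (method, `lower_value`
#'   actually applied, `channel_role`) and `warnings` (character; non-fatal
#'   QC notes such as an empty or full-frame mask).
#' @export
threshold_mask <- function(image, method = c("manual", "otsu"),
                           manual_value = NULL) {
  stopifnot(inherits(image, "nmj_image"))
  method <- match.arg(method)
  px <- image$pixels
  if (method == "manual") {
    if (is.null(manual_value)) stop("manual thresholding requires manual_value")
    lv <- manual_value
  } else {
    lv <- otsu_threshold(px)
  }
  fg <- px >= lv
  warnings <- character(0)
  if (!any(fg)) warnings <- c(warnings, "empty_mask")
  if (all(fg)) warnings <- c(warnings, "full_frame_mask")
  list(mask = nmj_mask(fg, image$calibration_um_per_px),
       record = list(method = method, lower_value = lv,
                     channel_role = image$channel_role),
       warnings = warnings)
}

#' Otsu's threshold (between-class variance maximization)
#'
#' Returns the lower bound of the foreground class: the split is
#' `background < t <= foreground`, maximizing the between-class variance
#' over all candidate splits of the observed intensity values.
#'
#' @param px numeric matrix or vector of intensities.
#' @return the computed lower threshold value.
#' @export
otsu_threshold <- function(px) {
  v <- sort(unique(as.vector(px)))
  if (length(v) == 1L) return(v)
  x <- as.vector(px)
  n <- length(x)
  # class split at candidate t: {x < t} vs {x >= t}, t in v[-1]
  cnt <- tabulate(match(x, v), nbins = length(v))
  csum_n <- cumsum(cnt)
  csum_x <- cumsum(cnt * v)
  tot <- csum_x[length(v)]
  k <- seq_len(length(v) - 1L)          # split after value v[k]
  w0 <- csum_n[k] / n
  w1 <- 1 - w0
  mu0 <- csum_x[k] / csum_n[k]
  mu1 <- (tot - csum_x[k]) / (n - csum_n[k])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  v[which.max(bcv) + 1L]
}

.label_mask <- function(mask, connectivity = 8L) {
  cpp_label(.mask_int(mask), as.integer(connectivity))
}

#' Fill enclosed background holes
#'
#' Every background region not 4-connected to the image border becomes
#' foreground. Monotone (output is a superset of the input) and idempotent.
#' A particle lying entirely inside a hole of another is absorbed into the
#' filled region.
#'
#' @param mask an [nmj_mask].
#' @return an [nmj_mask] with holes filled.
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "nmj_mask"))
  bg <- !mask$pixels
  lab <- cpp_label(matrix(as.integer(bg), nrow(bg), ncol(bg)), 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  filled <- mask$pixels | (lab > 0 & !(lab %in% border))
  nmj_mask(filled, mask$calibration_um_per_px)
}

#' Split touching particles by distance-transform watershed
#'
#' The binary analogue of ImageJ's "Watershed"/"segmented particles": seeds
#' are local maxima of the exact Euclidean distance transform (plateaus
#' merged, maxima closer than `min_seed_sep_px` merged), and basins are grown
#' by priority flood on decreasing distance. Every foreground pixel receives
#' a label, so the union of labels equals the mask; a convex blob is never
#' split.
#'
#' @param mask non-empty [nmj_mask].
#' @param min_seed_sep_px minimum Euclidean separation (pixels) between
#'   distinct seeds; closer maxima are merged into one seed.
#' @return an [nmj_labels] with consecutive labels `1..K`.
#' @export
watershed_split <- function(mask, min_seed_sep_px = 3) {
  stopifnot(inherits(mask, "nmj_mask"))
  m <- .mask_int(mask)
  if (!any(m == 1L)) stop("watershed_split: empty mask")
  d <- cpp_edt(m)
  seeds <- .watershed_seeds(d, m, min_seed_sep_px)
  lab <- cpp_watershed(d, seeds, m)
  # guard: relabel to consecutive ids in scan order
  u <- sort(unique(lab[lab > 0]))
  if (!identical(as.integer(u), seq_along(u))) {
    lab <- matrix(match(lab, c(0L, u)) - 1L, nrow(lab), ncol(lab))
  }
  nmj_labels(lab, mask$calibration_um_per_px)
}

# Seed detection for the binary watershed: regional maxima of the h-maxima
# transform of the EDT (reconstruction by dilation of EDT - h under the
# EDT, h = 2 px). The EDT ridge of a digital shape ripples by over a pixel
# (jagged digital boundaries on both sides of a ring or lobe), so STRICT
# regional maxima shatter one genuine peak into many seeds; the h-maxima
# transform levels any peak whose prominence is below h into a flat,
# connected plateau, while peaks separated by a saddle deeper than h (true
# multi-lobed particles, e.g. a dumbbell's two discs) stay distinct.
# Plateau pixels are merged by 8-connectivity; within each connected
# component of the mask, plateau groups whose closest pixels are within
# min_sep of each other are additionally merged (transitively). Merging
# never crosses mask components, so separate particles always keep separate
# seeds.
.watershed_seeds <- function(d, m, min_sep, h = 2) {
  nr <- nrow(d); nc <- ncol(d)
  dm <- ifelse(m == 1L, d, 0)
  hrec <- cpp_reconstruct(pmax(dm - h, 0), dm)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- ifelse(m == 1L, hrec, -Inf)
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  is_max <- m == 1L
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
    is_max <- is_max & (ctr >= nb)
  }
  sl <- cpp_label(matrix(as.integer(is_max), nr, nc), 8L)
  k <- max(sl)
  if (k > 1L && is.finite(min_sep) && min_sep > 0) {
    comp <- cpp_label(m, 8L)
    idx <- which(sl > 0)
    ri <- (idx - 1L) %% nr + 1L
    ci <- (idx - 1L) %/% nr + 1L
    gi <- sl[idx]
    gcomp <- comp[idx][match(seq_len(k), gi)]   # mask component per group
    parent <- seq_len(k)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (cc in unique(gcomp)) {
      grp <- which(gcomp == cc)
      ng <- length(grp)
      # a shattered component gets many seeds regardless; skip the O(ng^2)
      # merge there (it will be QC-flagged downstream anyway)
      if (ng < 2L || ng > 400L) next
      for (ai in seq_len(ng - 1L)) {
        a <- grp[ai]
        ra <- ri[gi == a]; ca <- ci[gi == a]
        for (bi in (ai + 1L):ng) {
          b <- grp[bi]
          rb <- ri[gi == b]; cb <- ci[gi == b]
          dd <- min(outer(ra, rb, "-")^2 + outer(ca, cb, "-")^2)
          if (dd <= min_sep^2) {
            fa <- find(a); fb <- find(b)
            if (fa != fb) parent[max(fa, fb)] <- min(fa, fb)
          }
        }
      }
    }
    root <- vapply(seq_len(k), find, integer(1))
    sl[sl > 0] <- match(root, sort(unique(root)))[sl[sl > 0]]
  }
  sl
}

#' Construct the endplate footprint
#'
#' A single connected region containing the whole AChR mask, standing for the
#' endplate territory. `convex_hull` (default) rasterizes the convex hull of
#' the foreground pixels; `close_fill` applies morphological closing with a
#' disc of `close_radius_px` and then fills holes (and, if the closing left
#' several components, takes their convex hull to guarantee connectivity).
#'
#' @param achr_mask non-empty [nmj_mask].
#' @param method `"convex_hull"` or `"close_fill"`.
#' @param close_radius_px closing radius in pixels (used by `close_fill`).
#' @return an [nmj_mask]: connected, a superset of `achr_mask`, idempotent
#'   under re-application.
#' @export
build_footprint <- function(achr_mask, method = c("convex_hull", "close_fill"),
                            close_radius_px = 5L) {
  stopifnot(inherits(achr_mask, "nmj_mask"))
  method <- match.arg(method)
  if (!any(achr_mask$pixels)) stop("build_footprint: empty AChR mask")
  if (method == "convex_hull") {
    fp <- .convex_hull_mask(achr_mask$pixels)
  } else {
    closed <- .binary_close(achr_mask$pixels, close_radius_px)
    fp <- fill_holes(nmj_mask(closed, achr_mask$calibration_um_per_px))$pixels
    if (max(cpp_label(matrix(as.integer(fp), nrow(fp), ncol(fp)), 8L)) > 1L)
      fp <- .convex_hull_mask(fp)
  }
  nmj_mask(fp | achr_mask$pixels, achr_mask$calibration_um_per_px)
}

# Rasterized convex hull: hull of pixel-center coordinates, pixel kept when
# its center is inside. Using centers (not corners) makes the operation
# exactly idempotent: newly added pixels have centers inside the hull, so
# they contribute no new extreme points on re-application.
.convex_hull_mask <- function(px) {
  idx <- which(px)
  nr <- nrow(px); nc <- ncol(px)
  ri <- (idx - 1L) %% nr + 1L
  ci <- (idx - 1L) %/% nr + 1L
  pts <- cbind(r = ri, c = ci)
  h <- grDevices::chull(pts[, "c"], pts[, "r"])
  hr <- pts[h, "r"]; hc <- pts[h, "c"]
  out <- matrix(FALSE, nr, nc)
  # convex polygon scanline fill at pixel-center rows
  nh <- length(h)
  for (r in seq_len(nr)) {
    xs <- numeric(0)
    for (e in seq_len(nh)) {
      r1 <- hr[e]; c1 <- hc[e]
      r2 <- hr[if (e == nh) 1L else e + 1L]; c2 <- hc[if (e == nh) 1L else e + 1L]
      if ((r1 <= r && r2 > r) || (r2 <= r && r1 > r)) {
        xs <- c(xs, c1 + (r - r1) / (r2 - r1) * (c2 - c1))
      } else if (r1 == r && r2 == r) {
        xs <- c(xs, c1, c2)
      }
    }
    if (length(xs) >= 2L) {
      lo <- min(xs); hi <- max(xs)
      cols <- seq_len(nc)
      out[r, cols >= lo & cols <= hi] <- TRUE
    }
  }
  out
}

.disc_kernel <- function(radius) {
  r <- max(1L, as.integer(radius))
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= r^2, , drop = FALSE]
}

.binary_dilate <- function(px, radius) {
  k <- .disc_kernel(radius)
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(k))) {
    di <- k$di[i]; dj <- k$dj[i]
    sr <- max(1L, 1L - di):min(nr, nr - di)
    sc <- max(1L, 1L - dj):min(nc, nc - dj)
    out[sr + di, sc + dj] <- out[sr + di, sc + dj] | px[sr, sc]
  }
  out
}

.binary_erode <- function(px, radius) {
  !.binary_dilate(!px, radius)
}

.binary_close <- function(px, radius) {
  # pad so dilation does not clip at the border before eroding back
  r <- max(1L, as.integer(radius))
  nr <- nrow(px); nc <- ncol(px)
  big <- matrix(FALSE, nr + 2L * r, nc + 2L * r)
  big[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- px
  closed <- .binary_erode(.binary_dilate(big, r), r)
  closed[(r + 1L):(r + nr), (r + 1L):(r + nc)]
}

#' Check a watershed segmentation for aberrance
#'
#' Automated stand-in for the interactive "confirm segmentation" step: the
#' segmentation is flagged aberrant (the "spider web"/"broken windows"
#' pattern) when the number of particles lying within the footprint exceeds
#' `max_clusters`, or the median particle area falls below
#' `min_cluster_area_um2`, or there are no particles at all. Cluster counting
#' must be withheld for flagged images; all other variables remain valid.
#'
#' @param labels [nmj_labels] from [watershed_split].
#' @param footprint [nmj_mask] endplate footprint.
#' @param max_clusters flag when more particles than this lie in the
#'   footprint (default 50).
#' @param min_cluster_area_um2 flag when the median particle area (um^2) is
#'   below this (default 0.25).
#' @return list (`nmj_segqc`): `aberrant`, `reason`, `particle_count`,
#'   `median_particle_area_um2`.
#' @export
check_segmentation <- function(labels, footprint, max_clusters = 50L,
                               min_cluster_area_um2 = 0.25) {
  stopifnot(inherits(labels, "nmj_labels"), inherits(footprint, "nmj_mask"))
  lb <- labels$labels
  cal2 <- labels$calibration_um_per_px^2
  inside <- lb[footprint$pixels & lb > 0]
  k_in <- length(unique(inside))
  sizes <- tabulate(lb[lb > 0], nbins = max(lb, 1L))
  med_area <- if (any(sizes > 0)) stats::median(sizes[sizes > 0]) * cal2 else
    NA_real_
  if (max(lb) == 0L) {
    qc <- list(aberrant = TRUE, reason = "no particles",
               particle_count = 0L, median_particle_area_um2 = NA_real_)
  } else if (k_in > max_clusters) {
    qc <- list(aberrant = TRUE,
               reason = sprintf(
                 "particle count inside footprint (%d) exceeds %d",
                 k_in, max_clusters),
               particle_count = k_in, median_particle_area_um2 = med_area)
  } else if (is.finite(med_area) && med_area < min_cluster_area_um2) {
    qc <- list(aberrant = TRUE,
               reason = sprintf(
                 "median particle area %.3g um2 below %.3g um2",
                 med_area, min_cluster_area_um2),
               particle_count = k_in, median_particle_area_um2 = med_area)
  } else {
    qc <- list(aberrant = FALSE, reason = "",
               particle_count = k_in, median_particle_area_um2 = med_area)
  }
  structure(qc, class = "nmj_segqc")
}
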