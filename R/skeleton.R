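# Skeletonization and branch statistics of the nerve terminal.

#' Topology-preserving skeletonization
#'
#' Zhang-Suen thinning to an (approximately) 1-px-wide, 8-connected medial
#' skeleton. Idempotent, and the skeleton is a subset of the mask.
#'
#' @param mask non-empty [nmj_mask].
#' @return an [nmj_mask] holding the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "nmj_mask"))
  if (!any(mask$pixels)) stop("skeletonize: empty mask")
  thin <- cpp_thin(.mask_int(mask))
  nmj_mask(thin == 1L, mask$calibration_um_per_px)
}

# Degree of every skeleton pixel in the pruned skeleton graph: 8-neighbour
# adjacency, minus diagonal edges that short-cut an orthogonal two-step path
# (the same convention branch lengths use). Raw 8-neighbour counts would
# misclassify the tips of a one-pixel-armed cross as branch points, because
# each tip diagonally touches the two neighbouring arms.
.neighbor_counts <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  sh <- function(di, dj) pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  deg <- matrix(0L, nr, nc)
  # orthogonal edges always count
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
    deg <- deg + (px & sh(d[1], d[2]))
  # diagonal edges only when no shared orthogonal neighbour short-cuts them
  for (d in list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    pair <- px & sh(d[1], d[2])
    cut <- sh(d[1], 0) | sh(0, d[2])
    deg <- deg + (pair & !cut)
  }
  deg
}

#' Classify skeleton pixels and count branches
#'
#' Neighbour-count classification in the style of the Binary Connectivity
#' plugin: an end point has exactly one neighbour in the skeleton graph, a
#' branch point three or more. The graph is the 8-neighbour adjacency with
#' diagonal short-cut edges removed (see [branch_lengths]), so the tip of a
#' one-pixel arm counts as an end point even where it diagonally touches the
#' neighbouring arms. Adjacent branch-point pixels (thinning's junction
#' clusters) are merged into a single branch point. Terminal branches are the
#' 8-connected segments that remain after deleting all branch-point pixels.
#' Spurs shorter than `prune_spurs_px` (segments touching an end point) are
#' discarded before counting, to suppress 1-2 px thinning artifacts; 0
#' disables pruning.
#'
#' @param skel 1-px-wide skeleton ([nmj_mask], from [skeletonize]).
#' @param prune_spurs_px drop terminal segments with fewer pixels than this.
#' @return list: `n_terminal_branches`, `n_branch_points`, `n_end_points`,
#'   and `segments` (label matrix of the counted segments).
#' @export
classify_skeleton <- function(skel, prune_spurs_px = 0L) {
  stopifnot(inherits(skel, "nmj_mask"))
  px <- skel$pixels
  if (!any(px)) stop("classify_skeleton: empty skeleton")
  cnt <- .neighbor_counts(px)
  branch_px <- px & cnt >= 3L
  seg_px <- px & !branch_px
  seg_lab <- .label_segments(seg_px, px)

  if (prune_spurs_px > 0L && max(seg_lab) > 0L) {
    ends <- px & cnt == 1L
    sizes <- tabulate(seg_lab[seg_lab > 0], nbins = max(seg_lab))
    has_end <- unique(seg_lab[ends & seg_lab > 0])
    drop <- intersect(which(sizes < prune_spurs_px), has_end)
    if (length(drop)) {
      px[seg_lab %in% drop] <- FALSE
      # re-thin implicit junction stubs and reclassify
      cnt <- .neighbor_counts(px)
      branch_px <- px & cnt >= 3L
      seg_px <- px & !branch_px
      seg_lab <- .label_segments(seg_px, px)
    }
  }

  bp_lab <- cpp_label(matrix(as.integer(branch_px), nrow(px), ncol(px)), 8L)
  ends <- px & cnt == 1L
  list(n_terminal_branches = max(seg_lab),
       n_branch_points = max(bp_lab),
       n_end_points = sum(ends),
       pruned = structure(list(pixels = px,
                               calibration_um_per_px =
                                 skel$calibration_um_per_px),
                          class = "nmj_mask"),
       segments = seg_lab)
}

# Label the segment pixels under the pruned skeleton-graph adjacency.
# Two arms meeting at a (deleted) junction pixel touch each other
# diagonally around it; under plain 8-connectivity labeling they would fuse
# back into one segment. Diagonal links are therefore only honoured when
# they are genuine graph edges, i.e. not short-cuts past an orthogonal
# neighbour of the FULL skeleton.
.label_segments <- function(seg_px, full_px) {
  nr <- nrow(seg_px); nc <- ncol(seg_px)
  idx <- which(seg_px)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  id <- match(seq_len(nr * nc), idx)      # pixel -> node index
  parent <- seq_along(idx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  unite <- function(a, b) {
    fa <- find(a); fb <- find(b)
    if (fa != fb) parent[max(fa, fb)] <<- min(fa, fb)
  }
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- seg_px
  padf <- matrix(FALSE, nr + 2L, nc + 2L)
  padf[2:(nr + 1L), 2:(nc + 1L)] <- full_px
  sh <- function(p, di, dj) p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  link <- function(pair_mask, di, dj) {
    for (p in which(pair_mask)) {
      q <- p + di + dj * nr
      unite(id[p], id[q])
    }
  }
  link(seg_px & sh(pad, 0, 1), 0L, 1L)                     # east
  link(seg_px & sh(pad, 1, 0), 1L, 0L)                     # south
  se <- seg_px & sh(pad, 1, 1) &
    !(sh(padf, 0, 1) | sh(padf, 1, 0))
  link(se, 1L, 1L)
  sw <- seg_px & sh(pad, 1, -1) &
    !(sh(padf, 0, -1) | sh(padf, 1, 0))
  link(sw, 1L, -1L)
  roots <- vapply(seq_along(idx), find, integer(1))
  lab[idx] <- match(roots, sort(unique(roots)))
  lab
}

#' Total and average branch length of a skeleton
#'
#' Length is the sum of 8-neighbour skeleton-graph steps (1 for orthogonal,
#' sqrt(2) for diagonal) after removing diagonal steps that short-cut an
#' orthogonal two-step path, times the calibration. The average divides by
#' the terminal-branch count from [classify_skeleton].
#'
#' @param skel [nmj_mask] skeleton.
#' @param prune_spurs_px passed to [classify_skeleton].
#' @return named numeric vector `c(total_um, average_um)` (`average_um` is
#'   `NA` when there are no branches).
#' @export
branch_lengths <- function(skel, prune_spurs_px = 0L) {
  cls <- classify_skeleton(skel, prune_spurs_px = prune_spurs_px)
  total <- .skeleton_length_px(cls$pruned$pixels) * skel$calibration_um_per_px
  avg <- if (cls$n_terminal_branches > 0) total / cls$n_terminal_branches else
    NA_real_
  c(total_um = total, average_um = avg)
}

# Chain length of the skeleton graph: each adjacent pixel pair contributes
# one step; a diagonal pair sharing an orthogonal skeleton neighbour is
# dropped (it duplicates the two orthogonal steps through that neighbour).
.skeleton_length_px <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(FALSE, nr + 1L, nc + 1L)
  pad[seq_len(nr), seq_len(nc)] <- px
  p <- pad[seq_len(nr), seq_len(nc)]
  east <- p & pad[seq_len(nr), seq_len(nc) + 1L]
  south <- p & pad[seq_len(nr) + 1L, seq_len(nc)]
  se <- p & pad[seq_len(nr) + 1L, seq_len(nc) + 1L]
  # shortcut check for SE pair (r,c)-(r+1,c+1): via (r,c+1) or (r+1,c)
  se_cut <- pad[seq_len(nr), seq_len(nc) + 1L] |
    pad[seq_len(nr) + 1L, seq_len(nc)]
  sw <- matrix(FALSE, nr, nc)
  sw_cut <- matrix(FALSE, nr, nc)
  if (nc > 1L) {
    sw[, 2:nc] <- p[, 2:nc] & pad[seq_len(nr) + 1L, 1:(nc - 1L)]
    # shortcut for SW pair (r,c)-(r+1,c-1): via (r,c-1) or (r+1,c)
    sw_cut[, 2:nc] <- pad[seq_len(nr), 1:(nc - 1L)] |
      pad[seq_len(nr) + 1L, 2:nc]
  }
  sum(east) + sum(south) + sqrt(2) * (sum(se & !se_cut) + sum(sw & !sw_cut))
}

#' Pre-synaptic arborization complexity score
#'
#' `log10(n_terminal_branches * n_branch_points * total_branch_length_um /
#' 100)`. Returns `NA` (rather than `-Inf`) when any factor is zero, so the
#' degenerate NMJ stays representable in a numeric results column.
#'
#' @param n_terminal_branches,n_branch_points,total_branch_length_um the
#'   three factors.
#' @return the complexity score, or `NA_real_` if any factor is 0 or missing.
#' @export
complexity <- function(n_terminal_branches, n_branch_points,
                       total_branch_length_um) {
  f <- c(n_terminal_branches, n_branch_points, total_branch_length_um)
  if (any(is.na(f)) || any(f == 0)) return(NA_real_)
  log10(n_terminal_branches * n_branch_points * total_branch_length_um / 100)
}
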