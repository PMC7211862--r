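# Synthetic two-channel NMJ fixtures with analytic ground truth. The stated
# world: an endplate of disc/annulus AChR clusters (optionally one cluster
# fully enclosed in another's hole, optionally extraneous background
# particles far from the endplate), a branched nerve terminal rendered as a
# stroked polyline tree on the 45-degree lattice, an axon stub approaching
# the tree root, additive Gaussian background noise, and a 3-slice z-stack
# whose per-slice attenuation makes the maximum projection recover the full
# signal. Rasterization rule: a pixel is foreground iff its center lies
# inside the analytic shape (boundary inclusive).

#' Cluster specification for the synthetic endplate
#'
#' @param center `(row, col)` center in pixels.
#' @param radius outer radius (px).
#' @param hole_radius radius of a central hole (0 = solid disc).
#' @param extraneous if `TRUE`, the particle is background debris outside
#'   the endplate (excluded from every ground-truth metric).
#' @return cluster spec (plain list).
#' @export
nmj_cluster <- function(center, radius, hole_radius = 0, extraneous = FALSE) {
  stopifnot(length(center) == 2L, radius > 0, hole_radius >= 0,
            hole_radius < radius)
  list(center = as.numeric(center), radius = radius,
       hole_radius = hole_radius, extraneous = extraneous)
}

#' Full synthetic NMJ specification
#'
#' @param frame `(rows, cols)` image size in pixels.
#' @param calibration_um_per_px pixel size (default 0.1 um, a typical
#'   confocal 63x sampling).
#' @param clusters list of [nmj_cluster] specs.
#' @param tree list of segments, each `list(from = c(r, c), to = c(r, c))`;
#'   segment endpoints meeting at a node of degree >= 3 form a branch point.
#' @param nerve_width_px stroke width of the rendered terminal branches.
#' @param axon `list(from, to, width_px)`: stub drawn from `from` towards
#'   the tree root, stopping `3` px short of `to` so the manual erase
#'   removes it exactly; `NULL` for no stub.
#' @param noise_sigma additive Gaussian noise s.d. (intensity units).
#' @param background,signal background and stain intensity levels (8-bit).
#' @param n_slices z-stack depth; slice attenuation profile peaks at 1 so
#'   the maximum projection recovers the full-intensity image.
#' @return an object of class `nmj_spec`.
#' @export
nmj_spec <- function(frame = c(300L, 300L), calibration_um_per_px = 0.1,
                     clusters = list(), tree = list(), nerve_width_px = 3,
                     axon = NULL, noise_sigma = 6, background = 24,
                     signal = 220, n_slices = 3L) {
  .check_cal(calibration_um_per_px)
  stopifnot(length(frame) == 2L, all(frame >= 32L), noise_sigma >= 0,
            background >= 0, signal > background, n_slices >= 1L)
  structure(list(frame = as.integer(frame),
                 calibration_um_per_px = calibration_um_per_px,
                 clusters = clusters, tree = tree,
                 nerve_width_px = nerve_width_px, axon = axon,
                 noise_sigma = noise_sigma, background = background,
                 signal = signal, n_slices = as.integer(n_slices)),
            class = "nmj_spec")
}

.grid_d2 <- function(nr, nc, center) {
  outer((seq_len(nr) - center[1])^2, (seq_len(nc) - center[2])^2, "+")
}

.render_clusters <- function(spec, include_extraneous = TRUE) {
  nr <- spec$frame[1]; nc <- spec$frame[2]
  out <- matrix(FALSE, nr, nc)
  for (cl in spec$clusters) {
    if (cl$extraneous && !include_extraneous) next
    d2 <- .grid_d2(nr, nc, cl$center)
    inside <- d2 <= cl$radius^2
    if (cl$hole_radius > 0) inside <- inside & d2 > cl$hole_radius^2
    out <- out | inside
  }
  out
}

.render_stroke <- function(px, from, to, width) {
  nr <- nrow(px); nc <- ncol(px)
  r0 <- max(1L, floor(min(from[1], to[1]) - width))
  r1 <- min(nr, ceiling(max(from[1], to[1]) + width))
  c0 <- max(1L, floor(min(from[2], to[2]) - width))
  c1 <- min(nc, ceiling(max(from[2], to[2]) + width))
  rr <- r0:r1; cc <- c0:c1
  v <- to - from
  vv <- sum(v^2)
  pr <- matrix(rr, length(rr), length(cc)) - from[1]
  pc <- matrix(cc, length(rr), length(cc), byrow = TRUE) - from[2]
  t <- if (vv > 0) pmin(pmax((pr * v[1] + pc * v[2]) / vv, 0), 1) else 0
  d2 <- (pr - t * v[1])^2 + (pc - t * v[2])^2
  px[rr, cc] <- px[rr, cc] | (d2 <= (width / 2)^2)
  px
}

.render_tree <- function(spec) {
  px <- matrix(FALSE, spec$frame[1], spec$frame[2])
  for (s in spec$tree)
    px <- .render_stroke(px, s$from, s$to, spec$nerve_width_px)
  px
}

.render_axon_stub <- function(spec) {
  px <- matrix(FALSE, spec$frame[1], spec$frame[2])
  ax <- spec$axon
  if (is.null(ax)) return(px)
  v <- ax$to - ax$from
  len <- sqrt(sum(v^2))
  # the stub (including its round cap) stays > 3 px clear of the tree root,
  # so the erase region below can cover it without touching the tree
  stop_at <- ax$from + v * max(0, len - (ax$width_px / 2 + 4)) / len
  .render_stroke(px, ax$from, stop_at, ax$width_px)
}

# Axon manual input implied by the spec: a diameter line straight across the
# stub at its midpoint, and a rectangular erase region covering the stub.
.axon_manual_input <- function(spec) {
  ax <- spec$axon
  if (is.null(ax)) return(NULL)
  v <- ax$to - ax$from
  len <- sqrt(sum(v^2))
  u <- v / len
  n <- c(-u[2], u[1])                 # unit normal
  mid <- ax$from + v * 0.5
  line <- rbind(mid - n * ax$width_px / 2, mid + n * ax$width_px / 2)
  m <- ax$width_px / 2 + 2            # margin around the stroke
  a <- ax$from - u * m
  b <- ax$to - u * 3                  # stops short: never clips the tree
  poly <- rbind(a + n * m, b + n * m, b - n * m, a - n * m)
  axon_input(line_endpoints = line, erase_region = poly)
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

#' Render a synthetic NMJ z-stack
#'
#' Deterministic for a given seed: channel 1 is the nerve terminal (tree +
#' axon stub), channel 2 the AChR staining (clusters incl. any extraneous
#' particles); both ride on a noisy background and are split over
#' `n_slices` attenuated slices whose maximum recovers the full image.
#'
#' @param spec an [nmj_spec].
#' @param seed RNG seed for the noise.
#' @return list: `stack` ([nmj_zstack], roles `nerve`, `achr`), `truth`
#'   (class `nmj_truth`: `spec`, `axon` ([axon_input] or NULL), `record`
#'   = [truth_metrics], `masks` = the rasterized true masks).
#' @export
generate_nmj <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "nmj_spec"))
  nr <- spec$frame[1]; nc <- spec$frame[2]
  achr_all <- .render_clusters(spec, include_extraneous = TRUE)
  nerve_all <- .render_tree(spec) | .render_axon_stub(spec)
  base_a <- spec$background + (spec$signal - spec$background) * achr_all
  base_n <- spec$background + (spec$signal - spec$background) * nerve_all

  nz <- spec$n_slices
  w <- if (nz == 1L) 1 else
    1 - 0.3 * (abs(seq_len(nz) - (nz + 1) / 2) / ((nz - 1) / 2))
  vox <- array(0, c(2L, nz, nr, nc))
  .with_seed(seed, {
    for (z in seq_len(nz)) {
      nzs <- if (spec$noise_sigma > 0)
        matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc) else 0
      vox[1L, z, , ] <- pmin(pmax(round(base_n * w[z] + nzs), 0), 255)
      nzs <- if (spec$noise_sigma > 0)
        matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc) else 0
      vox[2L, z, , ] <- pmin(pmax(round(base_a * w[z] + nzs), 0), 255)
    }
  })
  stack <- nmj_zstack(vox, spec$calibration_um_per_px, c("nerve", "achr"))
  truth <- structure(list(spec = spec, axon = .axon_manual_input(spec),
                          record = truth_metrics(spec),
                          masks = list(
                            achr = .render_clusters(spec, FALSE),
                            achr_all = achr_all,
                            nerve = .render_tree(spec))),
                     class = "nmj_truth")
  list(stack = stack, truth = truth)
}

#' Ground-truth metrics for a synthetic specification
#'
#' Integer metrics and stain areas come from closed forms (cluster geometry,
#' polyline tree, pi r^2); quantities without a useful closed form
#' (perimeters, Feret diameter, footprint measures, mask intersections) are
#' measured on the rasterized true masks - a path that bypasses the entire
#' image-processing chain (no noise, thresholding, watershed or thinning).
#' The attached `"tol"` attribute states the per-fixture discretization
#' tolerance for each continuous variable (see the methods vignette for the
#' derivations).
#'
#' @param spec an [nmj_spec].
#' @return named list of the 19 variables (class `nmj_truth_record`) with a
#'   `"tol"` attribute of absolute tolerances.
#' @export
truth_metrics <- function(spec) {
  stopifnot(inherits(spec, "nmj_spec"))
  cal <- spec$calibration_um_per_px
  cl <- Filter(function(x) !x$extraneous, spec$clusters)
  if (length(cl) == 0L) stop("truth_metrics: no endplate clusters in spec")

  # enclosure: disc i fully inside the hole of j is absorbed into j
  k <- length(cl)
  enclosed <- logical(k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j || cl[[j]]$hole_radius <= 0) next
    d <- sqrt(sum((cl[[i]]$center - cl[[j]]$center)^2))
    if (d + cl[[i]]$radius <= cl[[j]]$hole_radius) enclosed[i] <- TRUE
  }
  n_clusters <- sum(!enclosed)
  achr_area <- sum(vapply(cl, function(x)
    pi * (x$radius^2 - x$hole_radius^2), numeric(1))) * cal^2
  perim_px_analytic <- sum(vapply(cl, function(x)
    2 * pi * (x$radius + x$hole_radius), numeric(1)))

  # tree topology from exact endpoint matching
  segs <- spec$tree
  n_branches <- length(segs)
  nodes <- do.call(rbind, lapply(segs, function(s) rbind(s$from, s$to)))
  key <- paste(round(nodes[, 1], 6), round(nodes[, 2], 6))
  deg <- table(key)
  n_bp <- sum(deg >= 3)
  n_tips <- sum(deg == 1)
  seg_len_px <- vapply(segs, function(s) sqrt(sum((s$to - s$from)^2)),
                       numeric(1))
  total_len <- sum(seg_len_px) * cal
  avg_len <- if (n_branches > 0) total_len / n_branches else NA_real_

  # rasterized-truth measurements
  achr_mask <- nmj_mask(.render_clusters(spec, FALSE), cal)
  nerve_mask <- nmj_mask(.render_tree(spec), cal)
  amr <- measure_region(achr_mask)
  nmr <- measure_region(nerve_mask)
  fp <- build_footprint(achr_mask, "convex_hull")
  ep <- endplate_measures(fp)
  sc <- synaptic_contact(nerve_mask, achr_mask)
  comp_pct <- compactness(unname(amr["area_um2"]), unname(ep["area_um2"]))

  axon_um <- if (!is.null(spec$axon)) spec$axon$width_px * cal else NA_real_

  rec <- list(
    nerve_terminal_area_um2 = unname(nmr["area_um2"]),
    nerve_terminal_perimeter_um = unname(nmr["perimeter_um"]),
    n_terminal_branches = n_branches,
    n_branch_points = n_bp,
    total_branch_length_um = total_len,
    average_branch_length_um = avg_len,
    complexity = complexity(n_branches, n_bp, total_len),
    achr_area_um2 = achr_area,
    achr_perimeter_um = unname(amr["perimeter_um"]),
    endplate_area_um2 = unname(ep["area_um2"]),
    endplate_perimeter_um = unname(ep["perimeter_um"]),
    endplate_diameter_um = unname(ep["diameter_um"]),
    n_achr_clusters = n_clusters,
    average_cluster_area_um2 = achr_area / n_clusters,
    fragmentation = 1 - 1 / n_clusters,
    compactness_pct = comp_pct,
    overlap_pct = unname(sc["overlap_pct"]),
    synaptic_contact_area_um2 = unname(sc["contact_area_um2"]),
    axon_diameter_um = axon_um)

  # per-fixture discretization tolerances (absolute, in each variable's
  # units). Raster-path variables are exactly recoverable on a noise-free
  # fixture; they still carry a 2% allowance for the noisy case. Analytic
  # areas carry max(2%, one-pixel-band) and skeleton lengths carry the
  # tip/junction erosion term (see vignette).
  # tips erode by up to half the stroke width (+1 px quantization); at a
  # junction two strokes diverging by >= 45 degrees stay merged until their
  # lateral separation exceeds the width, shifting the skeleton junction by
  # up to w / tan(22.5 deg) ~ 2.5 w along the strokes
  w <- spec$nerve_width_px
  len_tol <- 0.02 * total_len +
    (n_tips * (w / 2 + 1) + 2.5 * w * n_bp) * cal
  tol <- c(
    nerve_terminal_area_um2 = 0.02 * rec$nerve_terminal_area_um2,
    nerve_terminal_perimeter_um = 0.02 * rec$nerve_terminal_perimeter_um,
    n_terminal_branches = 0, n_branch_points = 0,
    total_branch_length_um = len_tol,
    average_branch_length_um = if (n_branches > 0) len_tol / n_branches else
      NA_real_,
    complexity = log10(1 + len_tol / max(total_len, 1e-9)) + 1e-9,
    achr_area_um2 = max(0.02 * achr_area, perim_px_analytic * cal^2),
    achr_perimeter_um = 0.02 * rec$achr_perimeter_um,
    endplate_area_um2 = 0.02 * rec$endplate_area_um2,
    endplate_perimeter_um = 0.02 * rec$endplate_perimeter_um,
    endplate_diameter_um = 0.02 * rec$endplate_diameter_um,
    n_achr_clusters = 0,
    average_cluster_area_um2 = max(0.02 * achr_area, perim_px_analytic *
                                     cal^2) / n_clusters,
    fragmentation = 0,
    compactness_pct = 0.04 * comp_pct,
    overlap_pct = 0.02 * 100,
    synaptic_contact_area_um2 = 0.02 *
      max(rec$synaptic_contact_area_um2, rec$nerve_terminal_area_um2),
    axon_diameter_um = 1e-9)
  structure(rec, tol = tol, class = "nmj_truth_record")
}

#' Built-in fixture presets
#'
#' * `nominal`: 3 solid clusters + 1 annulus with a cluster enclosed in its
#'   hole, a 2-branch-point terminal tree with axon stub, Gaussian noise and
#'   one extraneous particle far outside the endplate.
#' * `enclosed`: the worked enclosure example - direct watershed particle
#'   count 5, fill-holes footprint count 4.
#' * `batch40`: 40 randomized noise-free nominal-style specs (no extraneous
#'   particles, no enclosure) for parameter-recovery runs.
#'
#' @param name `"nominal"`, `"enclosed"` or `"batch40"`.
#' @param seed seed controlling the randomized parts.
#' @return an [nmj_spec], or a list of 40 of them for `batch40`.
#' @export
nmj_preset <- function(name = c("nominal", "enclosed", "batch40"),
                       seed = 1L) {
  name <- match.arg(name)
  if (name == "enclosed") {
    return(nmj_spec(
      clusters = list(
        nmj_cluster(c(150, 150), radius = 18, hole_radius = 9),
        nmj_cluster(c(150, 150), radius = 4),      # enclosed in the hole
        nmj_cluster(c(118, 168), radius = 11),
        nmj_cluster(c(176, 176), radius = 10),
        nmj_cluster(c(182, 132), radius = 10)),
      tree = .preset_tree(c(130, 120)),
      axon = list(from = c(40, 60), to = c(130, 120), width_px = 4),
      noise_sigma = 0))
  }
  if (name == "nominal") {
    return(nmj_spec(
      clusters = list(
        nmj_cluster(c(150, 150), radius = 16, hole_radius = 8),
        nmj_cluster(c(150, 150), radius = 3.5),    # enclosed in the hole
        nmj_cluster(c(120, 170), radius = 12),
        nmj_cluster(c(178, 172), radius = 11),
        nmj_cluster(c(180, 126), radius = 10),
        nmj_cluster(c(40, 260), radius = 6, extraneous = TRUE)),
      tree = .preset_tree(c(130, 118)),
      axon = list(from = c(36, 58), to = c(130, 118), width_px = 4),
      noise_sigma = 6))
  }
  # batch40
  .with_seed(seed, lapply(seq_len(40L), function(i) .random_spec()))
}

.preset_tree <- function(root) {
  # trunk east, splitting twice; all segments on the 45-degree lattice
  j1 <- root + c(14, 28)
  j2 <- j1 + c(-24, 24)
  list(list(from = root, to = j1),
       list(from = j1, to = j2),
       list(from = j1, to = j1 + c(30, 30)),
       list(from = j2, to = j2 + c(-26, 0)),
       list(from = j2, to = j2 + c(0, 36)))
}

# One randomized batch40 spec: 2-5 chained clusters, a 1-3 branch-point
# tree on the 45-degree lattice, an axon stub, no noise.
.random_spec <- function() {
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  ctr <- c(150, 150)
  n_cl <- sample(2:5, 1)
  radii <- sample(10:14, n_cl, replace = TRUE)
  centers <- matrix(0, n_cl, 2)
  centers[1, ] <- ctr + stats::runif(2, -10, 10)
  if (n_cl > 1) for (i in 2:n_cl) {
    ok <- FALSE
    for (try in 1:50) {
      host <- sample(seq_len(i - 1L), 1)
      ang <- stats::runif(1, 0, 2 * pi)
      gap <- stats::runif(1, 4, 14)
      d <- radii[host] + radii[i] + gap
      cand <- centers[host, ] + d * c(cos(ang), sin(ang))
      clear <- all(sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                                   matrix(cand, i - 1L, 2, byrow = TRUE))^2))
                   >= radii[seq_len(i - 1L)] + radii[i] + 4)
      inb <- all(cand > 60) && all(cand < 240)
      if (clear && inb) { centers[i, ] <- cand; ok <- TRUE; break }
    }
    if (!ok) centers[i, ] <- centers[1, ] + c(0, radii[1] + radii[i] + 8)
  }
  clusters <- lapply(seq_len(n_cl), function(i)
    nmj_cluster(centers[i, ], radii[i]))

  # tree: trunk + one or two junctions, each splitting into two arms
  root <- ctr + stats::runif(2, -20, 20)
  d0 <- sample(1:8, 1)
  lens <- c(28, 36)
  trunk_end <- root + sample(lens, 1) * dirs[d0, ]
  segs <- list(list(from = root, to = trunk_end))
  n_bp <- sample(1:2, 1)
  arm_dirs <- c((d0 - 2) %% 8 + 1, d0 %% 8 + 1)   # +/- 45 degrees
  ends <- list()
  for (ad in arm_dirs) {
    e <- trunk_end + sample(lens, 1) * dirs[ad, ]
    segs[[length(segs) + 1L]] <- list(from = trunk_end, to = e)
    ends[[length(ends) + 1L]] <- list(end = e, dir = ad)
  }
  if (n_bp == 2) {
    pick <- ends[[sample(2, 1)]]
    arm2 <- c((pick$dir - 2) %% 8 + 1, pick$dir %% 8 + 1)
    for (ad in arm2) {
      e <- pick$end + sample(c(20, 28), 1) * dirs[ad, ]
      segs[[length(segs) + 1L]] <- list(from = pick$end, to = e)
    }
  }
  # out-of-frame guard: fall back to a fixed 45-degree-lattice tree
  allpts <- do.call(rbind, lapply(segs, function(s) rbind(s$from, s$to)))
  if (any(allpts < 12) || any(allpts > 288)) {
    root <- c(140, 130)
    j1 <- root + c(28, 28)
    segs <- list(list(from = root, to = j1),
                 list(from = j1, to = j1 + c(-28, 28)),
                 list(from = j1, to = j1 + c(36, 0)))
    d0 <- 4L                            # trunk direction of the fallback
  }

  w_ax <- sample(3:6, 1)
  # axon enters along the ray opposite the trunk, so neither the stub nor
  # its erase region can touch the arborization beyond the root
  entry <- root - 90 * dirs[d0, ]
  nmj_spec(clusters = clusters, tree = segs,
           nerve_width_px = sample(c(3, 5), 1),
           axon = list(from = entry, to = root, width_px = w_ax),
           noise_sigma = 0)
}

#' Generate an aberrant-segmentation fixture
#'
#' `spiderweb`: a large endplate plaque crazed by a fine dark lattice, so
#' watershed shatters it into hundreds of cells - the "spider web"/"broken
#' windows" pattern that must be QC-flagged. `low_quality`: signal barely
#' above a noisy background, yielding either a threshold-stage QC warning or
#' an aberrant speckle segmentation.
#'
#' @param kind `"spiderweb"` or `"low_quality"`.
#' @param seed RNG seed.
#' @return list as from [generate_nmj] (`truth` carries the spec only).
#' @export
generate_failure_case <- function(kind = c("spiderweb", "low_quality"),
                                  seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "spiderweb") {
    spec <- nmj_spec(clusters = list(nmj_cluster(c(150, 150), radius = 70)),
                     tree = .preset_tree(c(130, 120)),
                     noise_sigma = 4)
    out <- generate_nmj(spec, seed)
    # craze the AChR channel with a dark 7-px lattice over every slice
    nr <- spec$frame[1]; nc <- spec$frame[2]
    lines_r <- seq(5, nr, by = 7)
    lines_c <- seq(5, nc, by = 7)
    for (z in seq_len(spec$n_slices)) {
      sl <- out$stack$voxels[2, z, , ]
      sl[lines_r, ] <- spec$background
      sl[, lines_c] <- spec$background
      out$stack$voxels[2, z, , ] <- sl
    }
    out$truth$record <- NULL           # truth metrics void by construction
    return(out)
  }
  spec <- nmj_spec(clusters = list(nmj_cluster(c(150, 150), radius = 40),
                                   nmj_cluster(c(150, 210), radius = 20)),
                   tree = .preset_tree(c(130, 120)),
                   noise_sigma = 18, background = 30, signal = 55)
  out <- generate_nmj(spec, seed)
  out$truth$record <- NULL
  out
}

#' Write a fixture to disk (TIFF + truth sidecars)
#'
#' Writes `<name>.tif` (two channels interleaved over slices, ImageJ layout,
#' calibrated), `<name>_truth.json` (the ground-truth record) and appends the
#' axon manual input to `axon_sidecar.csv` in `dir`.
#'
#' @param gen output of [generate_nmj].
#' @param dir output directory (created if needed).
#' @param name fixture name (file stem / image id).
#' @return the TIFF path, invisibly.
#' @export
write_fixture <- function(gen, dir, name = "nmj") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stk <- gen$stack
  d <- dim(stk$voxels)
  pages <- list()
  for (z in seq_len(d[2])) for (ch in seq_len(d[1]))
    pages[[length(pages) + 1L]] <- matrix(stk$voxels[ch, z, , ], d[3], d[4])
  path <- file.path(dir, paste0(name, ".tif"))
  write_tiff(pages, path, stk$calibration_um_per_px,
             channels = d[1], slices = d[2])
  if (!is.null(gen$truth$record)) {
    jsonlite::write_json(
      gen$truth$record[!vapply(gen$truth$record, is.null, logical(1))],
      file.path(dir, paste0(name, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
  }
  ax <- gen$truth$axon
  if (!is.null(ax)) {
    rows <- data.frame()
    if (!is.null(ax$line_endpoints))
      rows <- rbind(rows, data.frame(image_id = name, kind = "line",
                                     point = 1:2,
                                     row = ax$line_endpoints[, 1] - 1,
                                     col = ax$line_endpoints[, 2] - 1))
    if (!is.null(ax$erase_region))
      rows <- rbind(rows, data.frame(image_id = name, kind = "erase",
                                     point = seq_len(nrow(ax$erase_region)),
                                     row = ax$erase_region[, 1] - 1,
                                     col = ax$erase_region[, 2] - 1))
    sc <- file.path(dir, "axon_sidecar.csv")
    utils::write.table(rows, sc, sep = ",", row.names = FALSE,
                       col.names = !file.exists(sc), append = file.exists(sc))
  }
  invisible(path)
}
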