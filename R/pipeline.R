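# The guided seven-stage analysis flow, single-image and batch drivers,
# record assembly and internal consistency checking.

#' Pipeline run configuration
#'
#' Validated, fully-defaulted configuration for [analyze_image] /
#' [analyze_folder]. All geometric defaults are in pixels; QC defaults in
#' micrometre units.
#'
#' @param channel_map named integer vector: roles `nerve` and `achr` to
#'   1-based channel indices.
#' @param calibration_um_per_px optional calibration override used when the
#'   TIFF carries none.
#' @param threshold_method `"otsu"` or `"manual"`.
#' @param threshold_nerve,threshold_achr manual threshold values (required
#'   when `threshold_method = "manual"`).
#' @param footprint_method `"convex_hull"` or `"close_fill"`.
#' @param footprint_close_radius_px closing radius for `close_fill`.
#' @param qc_max_clusters,qc_min_cluster_area_um2 aberrance thresholds, see
#'   [check_segmentation].
#' @param endplate_join_radius_px closing radius used to group AChR particles
#'   into the endplate structure (extraneous-particle exclusion).
#' @param min_particle_px particles smaller than this (pixels) are treated as
#'   background debris and dropped from both masks before measurement.
#' @param prune_spurs_px skeleton spur suppression, see [classify_skeleton].
#' @param min_seed_sep_px watershed seed separation, see [watershed_split].
#' @param cluster_within `"centroid"` or `"subset"`, see [count_clusters].
#' @param interactive reserved for interactive confirmation prompts (the
#'   headless default applies the automated QC heuristics).
#' @param verbose log stage boundaries to stderr.
#' @return an object of class `nmj_config`.
#' @export
nmj_config <- function(channel_map = c(nerve = 1L, achr = 2L),
                       calibration_um_per_px = NULL,
                       threshold_method = c("otsu", "manual"),
                       threshold_nerve = NULL, threshold_achr = NULL,
                       footprint_method = c("convex_hull", "close_fill"),
                       footprint_close_radius_px = 5L,
                       qc_max_clusters = 50L,
                       qc_min_cluster_area_um2 = 0.25,
                       endplate_join_radius_px = 10L,
                       min_particle_px = 4L,
                       prune_spurs_px = 2L,
                       min_seed_sep_px = 3,
                       cluster_within = c("centroid", "subset"),
                       interactive = FALSE,
                       verbose = FALSE) {
  threshold_method <- match.arg(threshold_method)
  footprint_method <- match.arg(footprint_method)
  cluster_within <- match.arg(cluster_within)
  stopifnot(all(c("nerve", "achr") %in% names(channel_map)))
  if (!is.null(calibration_um_per_px)) .check_cal(calibration_um_per_px)
  if (threshold_method == "manual" &&
      (is.null(threshold_nerve) || is.null(threshold_achr)))
    stop("manual thresholding requires threshold_nerve and threshold_achr")
  stopifnot(qc_max_clusters >= 1, qc_min_cluster_area_um2 >= 0,
            endplate_join_radius_px >= 0, min_particle_px >= 0,
            prune_spurs_px >= 0)
  structure(list(channel_map = channel_map,
                 calibration_um_per_px = calibration_um_per_px,
                 threshold_method = threshold_method,
                 threshold_nerve = threshold_nerve,
                 threshold_achr = threshold_achr,
                 footprint_method = footprint_method,
                 footprint_close_radius_px = footprint_close_radius_px,
                 qc_max_clusters = qc_max_clusters,
                 qc_min_cluster_area_um2 = qc_min_cluster_area_um2,
                 endplate_join_radius_px = endplate_join_radius_px,
                 min_particle_px = min_particle_px,
                 prune_spurs_px = prune_spurs_px,
                 min_seed_sep_px = min_seed_sep_px,
                 cluster_within = cluster_within,
                 interactive = interactive,
                 verbose = verbose),
            class = "nmj_config")
}

#' Load a run configuration from YAML
#'
#' Recognized keys mirror the [nmj_config] arguments; nested ImageJ-style
#' keys (`threshold.method`, `threshold.value.nerve`, `threshold.value.achr`,
#' `footprint.method`, `footprint.close_radius_px`, `qc.max_clusters`,
#' `qc.min_cluster_area_um2`, `channels.nerve`, `channels.achr`,
#' `calibration_um_per_px`) are also accepted.
#'
#' @param path YAML file.
#' @return an `nmj_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  flat <- function(...) {
    v <- y
    for (k in c(...)) {
      if (is.null(v)) return(NULL)
      v <- v[[k]]
    }
    v
  }
  put <- function(name, value) if (!is.null(value)) args[[name]] <<- value
  ch <- c(nerve = flat("channels", "nerve"), achr = flat("channels", "achr"))
  if (length(ch) == 2L) put("channel_map", vapply(ch, as.integer, 1L))
  put("calibration_um_per_px", flat("calibration_um_per_px"))
  put("threshold_method", flat("threshold", "method"))
  put("threshold_nerve", flat("threshold", "value", "nerve"))
  put("threshold_achr", flat("threshold", "value", "achr"))
  put("footprint_method", flat("footprint", "method"))
  put("footprint_close_radius_px", flat("footprint", "close_radius_px"))
  put("qc_max_clusters", flat("qc", "max_clusters"))
  put("qc_min_cluster_area_um2", flat("qc", "min_cluster_area_um2"))
  for (k in c("endplate_join_radius_px", "min_particle_px", "prune_spurs_px",
              "min_seed_sep_px", "cluster_within", "interactive", "verbose"))
    put(k, y[[k]])
  do.call(nmj_config, args)
}

#' The seven pipeline stages
#'
#' @return character vector of the seven stage names, in execution order
#'   (the dry-run enumeration of the guided flow).
#' @export
nmj_stages <- function() {
  c("1/7 project channels",
    "2/7 threshold AChR channel",
    "3/7 threshold nerve channel",
    "4/7 axon measure/erase",
    "5/7 post-synaptic measures + endplate footprint",
    "6/7 segmentation check + cluster count",
    "7/7 assemble record")
}

.stage_log <- function(cfg, msg) {
  if (isTRUE(cfg$verbose)) message("[nmjmetrics] ", msg)
}

# Drop particles below min_px pixels (background debris).
.drop_small <- function(mask, min_px) {
  if (min_px <= 0L || !any(mask$pixels)) return(mask)
  lab <- .label_mask(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_px)
  nmj_mask(matrix(lab %in% keep, nrow(lab), ncol(lab)),
           mask$calibration_um_per_px)
}

# Select the endplate structure: particles whose edge-to-edge gap is at most
# twice the join radius are grouped (connectivity of the dilated mask), and
# the group holding the largest share of the staining is kept. Distant
# extraneous particles fall outside the group.
.select_endplate <- function(achr_mask, join_radius_px) {
  px <- achr_mask$pixels
  if (!any(px)) return(achr_mask)
  grown <- if (join_radius_px > 0L) .binary_dilate(px, join_radius_px) else px
  lab <- cpp_label(matrix(as.integer(grown), nrow(grown), ncol(grown)), 8L)
  k <- max(lab)
  if (k <= 1L) return(achr_mask)
  scores <- vapply(seq_len(k), function(i) sum(px[lab == i]), numeric(1))
  best <- which.max(scores)
  nmj_mask(px & (lab == best), achr_mask$calibration_um_per_px)
}

#' Analyse one NMJ image through the seven-stage flow
#'
#' Stages: (1) per-channel maximum-intensity projection, (2) AChR threshold,
#' (3) nerve threshold, (4) axon measure/erase, (5) post-synaptic measures
#' and endplate footprint, (6) segmentation check and cluster count, (7)
#' record assembly. Aberrant segmentation leaves the cluster-dependent fields
#' missing while every other variable is still measured and recorded; a
#' missing axon input leaves `axon_diameter_um` missing with a QC flag.
#'
#' @param stack an [nmj_zstack] with roles `nerve` and `achr`.
#' @param cfg an [nmj_config].
#' @param axon optional [axon_input].
#' @param image_id identifier recorded in the results row.
#' @return an `nmj_record`: the 19 variables plus provenance and QC flags.
#' @export
analyze_image <- function(stack, cfg = nmj_config(), axon = NULL,
                          image_id = "image") {
  stopifnot(inherits(stack, "nmj_zstack"), inherits(cfg, "nmj_config"))
  stages <- nmj_stages()
  qc_flags <- character(0)
  cal <- stack$calibration_um_per_px

  .stage_log(cfg, stages[1L])
  achr_img <- max_project(stack, "achr")
  nerve_img <- max_project(stack, "nerve")

  .stage_log(cfg, stages[2L])
  thr_a <- threshold_mask(achr_img, cfg$threshold_method,
                          manual_value = cfg$threshold_achr)
  if (length(thr_a$warnings))
    qc_flags <- c(qc_flags, paste0("achr_threshold_", thr_a$warnings))

  .stage_log(cfg, stages[3L])
  thr_n <- threshold_mask(nerve_img, cfg$threshold_method,
                          manual_value = cfg$threshold_nerve)
  if (length(thr_n$warnings))
    qc_flags <- c(qc_flags, paste0("nerve_threshold_", thr_n$warnings))

  .stage_log(cfg, stages[4L])
  axon_um <- NA_real_
  nerve_mask <- thr_n$mask
  if (!is.null(axon)) {
    if (!is.null(axon$line_endpoints)) axon_um <- axon_diameter(axon, cal)
    else qc_flags <- c(qc_flags, "no_axon_line")
    nerve_mask <- erase_axon(nerve_mask, axon)
  } else {
    qc_flags <- c(qc_flags, "no_axon_input")
  }
  nerve_mask <- .drop_small(nerve_mask, cfg$min_particle_px)

  .stage_log(cfg, stages[5L])
  achr_all <- .drop_small(thr_a$mask, cfg$min_particle_px)
  post <- list(achr_area_um2 = NA_real_, achr_perimeter_um = NA_real_,
               endplate_area_um2 = NA_real_, endplate_perimeter_um = NA_real_,
               endplate_diameter_um = NA_real_, compactness_pct = NA_real_,
               overlap_pct = NA_real_, synaptic_contact_area_um2 = NA_real_)
  pre <- list(nerve_terminal_area_um2 = NA_real_,
              nerve_terminal_perimeter_um = NA_real_,
              n_terminal_branches = NA_integer_, n_branch_points = NA_integer_,
              total_branch_length_um = NA_real_,
              average_branch_length_um = NA_real_, complexity = NA_real_)
  clusters <- list(n_clusters = NA_integer_,
                   average_cluster_area_um2 = NA_real_,
                   fragmentation = NA_real_)
  footprint <- NULL
  achr_ep <- NULL
  if (any(achr_all$pixels)) {
    achr_ep <- .select_endplate(achr_all, cfg$endplate_join_radius_px)
    footprint <- build_footprint(achr_ep, cfg$footprint_method,
                                 cfg$footprint_close_radius_px)
    ep <- endplate_measures(footprint)
    amr <- measure_region(achr_ep)
    post$achr_area_um2 <- unname(amr["area_um2"])
    post$achr_perimeter_um <- unname(amr["perimeter_um"])
    post$endplate_area_um2 <- unname(ep["area_um2"])
    post$endplate_perimeter_um <- unname(ep["perimeter_um"])
    post$endplate_diameter_um <- unname(ep["diameter_um"])
    post$compactness_pct <- compactness(post$achr_area_um2,
                                        post$endplate_area_um2)
  } else {
    qc_flags <- c(qc_flags, "empty_achr_mask")
  }
  if (any(nerve_mask$pixels)) {
    pre <- measure_nerve_terminal(nerve_mask,
                                  prune_spurs_px = cfg$prune_spurs_px)
    if (is.na(pre$complexity)) qc_flags <- c(qc_flags, "complexity_undefined")
  } else {
    qc_flags <- c(qc_flags, "empty_nerve_mask")
  }
  if (any(nerve_mask$pixels) && !is.null(achr_ep)) {
    sc <- synaptic_contact(nerve_mask, achr_ep)
    post$overlap_pct <- unname(sc["overlap_pct"])
    post$synaptic_contact_area_um2 <- unname(sc["contact_area_um2"])
  }

  .stage_log(cfg, stages[6L])
  if (!is.null(footprint)) {
    labels <- watershed_split(achr_ep, min_seed_sep_px = cfg$min_seed_sep_px)
    qc <- check_segmentation(labels, footprint,
                             max_clusters = cfg$qc_max_clusters,
                             min_cluster_area_um2 = cfg$qc_min_cluster_area_um2)
    if (qc$aberrant) {
      qc_flags <- c(qc_flags, paste0("aberrant_segmentation: ", qc$reason))
      clusters <- list(n_clusters = NA_integer_,
                       average_cluster_area_um2 = NA_real_,
                       fragmentation = NA_real_)
    } else {
      cs <- count_clusters(labels, achr_ep, footprint, qc = qc,
                           within = cfg$cluster_within)
      clusters <- cs[c("n_clusters", "average_cluster_area_um2",
                       "fragmentation")]
    }
  }

  .stage_log(cfg, stages[7L])
  rec <- c(pre, post[c("achr_area_um2", "achr_perimeter_um",
                       "endplate_area_um2", "endplate_perimeter_um",
                       "endplate_diameter_um")],
           list(n_achr_clusters = clusters$n_clusters,
                average_cluster_area_um2 = clusters$average_cluster_area_um2,
                fragmentation = clusters$fragmentation),
           post[c("compactness_pct", "overlap_pct",
                  "synaptic_contact_area_um2")],
           list(axon_diameter_um = axon_um,
                image_id = image_id,
                image_width_px = dim(stack$voxels)[4],
                image_height_px = dim(stack$voxels)[3],
                calibration_um_per_px = cal,
                threshold_method = cfg$threshold_method,
                threshold_nerve = thr_n$record$lower_value,
                threshold_achr = thr_a$record$lower_value,
                qc_flags = qc_flags))
  rec <- structure(rec, class = "nmj_record")
  validate_record(rec)
  rec
}

#' Internal consistency check of an analysis record
#'
#' Asserts the derived-variable identities on a record: average branch length
#' equals total/count, complexity matches its factors, fragmentation matches
#' the cluster count, average cluster area times count equals the AChR area,
#' and overlap equals contact / AChR area. Called on every record the
#' pipeline emits.
#'
#' @param rec an `nmj_record`.
#' @return `TRUE` invisibly; stops on an inconsistent record.
#' @export
validate_record <- function(rec) {
  stopifnot(inherits(rec, "nmj_record"))
  eq <- function(a, b) is.na(a) || is.na(b) || abs(a - b) < 1e-8
  with(rec, {
    if (!is.na(n_terminal_branches) && !is.na(average_branch_length_um) &&
        n_terminal_branches > 0 &&
        !eq(average_branch_length_um,
            total_branch_length_um / n_terminal_branches))
      stop("record inconsistency: average branch length")
    if (!is.na(complexity) &&
        !eq(complexity, log10(n_terminal_branches * n_branch_points *
                                total_branch_length_um / 100)))
      stop("record inconsistency: complexity")
    if (!is.na(n_achr_clusters)) {
      if (!eq(fragmentation, 1 - 1 / n_achr_clusters))
        stop("record inconsistency: fragmentation")
      if (!eq(average_cluster_area_um2 * n_achr_clusters, achr_area_um2))
        stop("record inconsistency: average cluster area")
    }
    if (!is.na(overlap_pct) && achr_area_um2 > 0 &&
        !eq(overlap_pct, synaptic_contact_area_um2 / achr_area_um2 * 100))
      stop("record inconsistency: overlap")
    if (!is.na(compactness_pct) && compactness_pct > 100 + 1e-8)
      stop("record inconsistency: compactness above 100%")
  })
  invisible(TRUE)
}

#' Batch-analyse a folder of TIFF images
#'
#' Files are processed in lexicographic order; a failing image is logged and
#' skipped without aborting the run.
#'
#' @param dir folder containing `.tif`/`.tiff` images.
#' @param cfg an [nmj_config].
#' @param axon_sidecar optional CSV of manual axon inputs (columns
#'   `image_id, kind, point, row, col`; `kind` is `line` or `erase`;
#'   coordinates 0-based pixel row/col).
#' @param thresholds optional CSV of per-image manual thresholds (columns
#'   `image_id, nerve_value, achr_value`), overriding the config method.
#' @param out optional path; when given the curated results CSV is written.
#' @return list of `nmj_record`s (invisibly also written to `out`).
#' @export
analyze_folder <- function(dir, cfg = nmj_config(), axon_sidecar = NULL,
                           thresholds = NULL, out = NULL) {
  files <- sort(list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop("no TIFF images found in ", dir)
  axons <- if (!is.null(axon_sidecar)) read_axon_sidecar(axon_sidecar) else
    list()
  thr <- if (!is.null(thresholds))
    utils::read.csv(thresholds, stringsAsFactors = FALSE) else NULL

  records <- list()
  for (f in files) {
    id <- sub("\\.tiff?$", "", basename(f), ignore.case = TRUE)
    res <- tryCatch({
      stk <- load_stack(f, cfg$channel_map, cfg$calibration_um_per_px)
      icfg <- cfg
      if (!is.null(thr) && id %in% thr$image_id) {
        row <- thr[thr$image_id == id, ][1L, ]
        icfg$threshold_method <- "manual"
        icfg$threshold_nerve <- row$nerve_value
        icfg$threshold_achr <- row$achr_value
      }
      analyze_image(stk, icfg, axon = axons[[id]], image_id = id)
    }, error = function(e) {
      message("[nmjmetrics] skipping ", basename(f), ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(res)) records[[length(records) + 1L]] <- res
  }
  if (length(records) == 0L) stop("no image in ", dir, " could be analysed")
  if (!is.null(out)) write_results(records, out)
  records
}

#' Read a manual-axon sidecar CSV
#'
#' @param path CSV with columns `image_id, kind, point, row, col` (`kind`
#'   `line` needs exactly 2 points, `erase` at least 3; `row`/`col` 0-based).
#' @return named list of [axon_input] objects, keyed by `image_id`.
#' @export
read_axon_sidecar <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("image_id", "kind", "point", "row", "col") %in% names(tab)))
  out <- list()
  for (id in unique(tab$image_id)) {
    sub <- tab[tab$image_id == id, ]
    line <- sub[sub$kind == "line", ]
    poly <- sub[sub$kind == "erase", ]
    line_m <- if (nrow(line)) {
      line <- line[order(line$point), ]
      cbind(line$row, line$col) + 1  # 0-based -> 1-based
    } else NULL
    poly_m <- if (nrow(poly)) {
      poly <- poly[order(poly$point), ]
      cbind(poly$row, poly$col) + 1
    } else NULL
    out[[as.character(id)]] <- axon_input(line_m, poly_m)
  }
  out
}
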