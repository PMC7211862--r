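# Concordance of two record sets, mirroring the manual-versus-automated
# validation design: per-variable correlation across matched images.

#' Per-variable concordance between two record sets
#'
#' For users validating this pipeline against reference output (e.g. a
#' manual workflow) on the same images: records are matched by `image_id`
#' and each of the 19 variables is correlated across images (Pearson and
#' Spearman).
#'
#' @param records_a,records_b lists of `nmj_record`s or data frames in the
#'   [records_to_table] layout, covering the same image ids.
#' @param variables which variables to compare (default: all 19).
#' @return data.frame: `variable`, `pearson_r`, `spearman_r`, `n` (number of
#'   complete pairs; correlations are `NA` when fewer than 3 pairs or a side
#'   is constant).
#' @export
validate_against_reference <- function(records_a, records_b,
                                       variables = nmj_variable_names()) {
  ta <- if (is.data.frame(records_a)) records_a else
    records_to_table(records_a)
  tb <- if (is.data.frame(records_b)) records_b else
    records_to_table(records_b)
  if (!setequal(ta$image_id, tb$image_id))
    stop("record sets cover different image ids")
  tb <- tb[match(ta$image_id, tb$image_id), ]
  res <- lapply(variables, function(v) {
    x <- as.numeric(ta[[v]]); y <- as.numeric(tb[[v]])
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      pr <- stats::cor(x[ok], y[ok], method = "pearson")
      sr <- stats::cor(x[ok], y[ok], method = "spearman")
    } else {
      pr <- NA_real_; sr <- NA_real_
    }
    data.frame(variable = v, pearson_r = pr, spearman_r = sr, n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a QC overlay PNG
#'
#' Grayscale AChR projection with the endplate footprint outline (green),
#' watershed particle boundaries (red) and the nerve mask (blue tint), for
#' eyeballing threshold and segmentation quality.
#'
#' @param path output PNG path.
#' @param achr_image [nmj_image] AChR projection.
#' @param footprint optional [nmj_mask].
#' @param labels optional [nmj_labels].
#' @param nerve_mask optional [nmj_mask].
#' @return `path`, invisibly.
#' @export
write_overlay <- function(path, achr_image, footprint = NULL, labels = NULL,
                          nerve_mask = NULL) {
  stopifnot(inherits(achr_image, "nmj_image"))
  px <- achr_image$pixels
  g <- px / max(px, 1)
  img <- array(rep(g, 3L), c(nrow(g), ncol(g), 3L))
  outline <- function(mask_px) {
    inner <- .binary_erode(mask_px, 1L)
    mask_px & !inner
  }
  if (!is.null(nerve_mask)) {
    img[, , 3][nerve_mask$pixels] <- pmin(1, img[, , 3][nerve_mask$pixels] +
                                            0.5)
  }
  if (!is.null(labels)) {
    lb <- labels$labels
    for (k in seq_len(max(lb))) {
      o <- outline(lb == k)
      img[, , 1][o] <- 1; img[, , 2][o] <- img[, , 2][o] * 0.3
      img[, , 3][o] <- img[, , 3][o] * 0.3
    }
  }
  if (!is.null(footprint)) {
    o <- outline(footprint$pixels)
    img[, , 2][o] <- 1; img[, , 1][o] <- img[, , 1][o] * 0.3
    img[, , 3][o] <- img[, , 3][o] * 0.3
  }
  png::writePNG(img, path)
  invisible(path)
}
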