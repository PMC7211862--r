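# Cluster counting, endplate measures and the derived fractions.

make_cluster_scene <- function(extra_outside = FALSE) {
  px <- disc_px(120, 120, c(40, 40), 9) | disc_px(120, 120, c(40, 75), 9) |
    disc_px(120, 120, c(75, 40), 9) | disc_px(120, 120, c(75, 75), 9)
  if (extra_outside) px <- px | disc_px(120, 120, c(112, 112), 5)
  px
}

test_that("count_clusters counts footprint particles with enclosure absorption", {
  cal <- 0.1
  # 4 disjoint discs inside the footprint
  px <- make_cluster_scene()
  m <- nmj_mask(px, cal)
  inner <- nmj_mask(make_cluster_scene(), cal)
  fp <- build_footprint(inner)
  cs <- count_clusters(watershed_split(m), m, fp)
  expect_equal(cs$n_clusters, 4L)
  expect_equal(cs$average_cluster_area_um2, sum(px) * cal^2 / 4)
  expect_equal(cs$fragmentation, 1 - 1 / 4)
  # annulus + enclosed disc + 3 discs: direct components 5, counted 4
  enc <- disc_px(120, 120, c(60, 60), 16, hole = 8) |
    disc_px(120, 120, c(60, 60), 4) |
    disc_px(120, 120, c(30, 85), 9) | disc_px(120, 120, c(90, 88), 9) |
    disc_px(120, 120, c(92, 32), 9)
  me <- nmj_mask(enc, cal)
  lbe <- watershed_split(me)
  expect_equal(max(lbe$labels), 5L)                 # direct watershed count
  fpe <- build_footprint(me)
  cse <- count_clusters(lbe, me, fpe)
  expect_equal(cse$n_clusters, 4L)                  # enclosure absorbed
  # extraneous particle outside the footprint is excluded
  pxx <- make_cluster_scene(extra_outside = TRUE)
  mx <- nmj_mask(pxx, cal)
  fpx <- build_footprint(inner)                     # endplate footprint only
  csx <- count_clusters(watershed_split(mx), mx, fpx)
  expect_equal(csx$n_clusters, 4L)
  # aberrant QC voids all cluster fields
  qc <- structure(list(aberrant = TRUE, reason = "x", particle_count = 99L,
                       median_particle_area_um2 = 0.01), class = "nmj_segqc")
  cs0 <- count_clusters(watershed_split(m), m, fp, qc = qc)
  expect_true(is.na(cs0$n_clusters) && is.na(cs0$fragmentation) &&
                is.na(cs0$average_cluster_area_um2))
})

test_that("fill-holes counting never exceeds the direct count (random scenes)", {
  set.seed(55)
  cal <- 0.1
  for (i in 1:30) {
    px <- matrix(FALSE, 80, 80)
    for (k in seq_len(sample(2:5, 1))) {
      ctr <- c(sample(15:65, 1), sample(15:65, 1))
      r <- sample(5:11, 1)
      hole <- if (runif(1) < 0.3) sample(2:(r - 3), 1) else 0
      px <- px | disc_px(80, 80, ctr, r, hole)
      if (hole >= 3 && runif(1) < 0.5)
        px <- px | disc_px(80, 80, ctr, max(1, hole - 2))
    }
    if (!any(px)) next
    m <- nmj_mask(px, cal)
    lb <- watershed_split(m)
    fp <- build_footprint(m)
    cs <- count_clusters(lb, m, fp)
    expect_lte(cs$n_clusters, max(lb$labels))
    # fragmentation bookkeeping
    expect_equal(cs$fragmentation, 1 - 1 / cs$n_clusters)
    expect_equal(cs$average_cluster_area_um2 * cs$n_clusters,
                 sum(px) * cal^2)
  }
})

test_that("endplate_measures bundles area, perimeter and Feret diameter", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  ep <- endplate_measures(nmj_mask(sq, 0.1))
  expect_equal(unname(ep["area_um2"]), 1.0)
  expect_equal(unname(ep["diameter_um"]), sqrt(200) * 0.1)
  # footprint identical to a single compact plaque: endplate area = AChR area
  d <- disc_px(50, 50, c(25, 25), 15)
  m <- nmj_mask(d, 0.1)
  fp <- build_footprint(m)
  ep2 <- endplate_measures(fp)
  expect_lte(abs(unname(ep2["area_um2"]) - sum(d) * 0.01), 0.06 * sum(d) * 0.01)
  expect_lt(abs(unname(ep2["diameter_um"]) - 2 * 15 * 0.1), 0.15)
})

test_that("compactness and synaptic_contact follow their defining ratios", {
  expect_equal(compactness(2.5, 5.0), 50)
  expect_equal(compactness(3, 3), 100)
  expect_error(compactness(0, 5), "positive")
  cal <- 0.1
  a <- matrix(FALSE, 20, 40); a[5:14, 3:12] <- TRUE; a[5:14, 25:34] <- TRUE
  achr <- nmj_mask(a, cal)
  # identical masks: full overlap
  sc <- synaptic_contact(achr, achr)
  expect_equal(unname(sc["overlap_pct"]), 100)
  expect_equal(unname(sc["contact_area_um2"]), sum(a) * cal^2)
  # disjoint masks
  n0 <- nmj_mask(matrix(FALSE, 20, 40), cal); n0$pixels[18, 38] <- TRUE
  expect_equal(unname(synaptic_contact(n0, achr)["overlap_pct"]), 0)
  # left particle only: contact = half the AChR area -> 50%
  left <- matrix(FALSE, 20, 40); left[, 1:20] <- TRUE
  sc3 <- synaptic_contact(nmj_mask(left, cal), achr)
  expect_equal(unname(sc3["overlap_pct"]), 50)
  expect_equal(unname(sc3["contact_area_um2"]), sum(a) * cal^2 / 2)
  # bounds on random masks
  set.seed(77)
  for (i in 1:15) {
    x <- matrix(runif(400) < 0.4, 20, 20)
    y <- matrix(runif(400) < 0.4, 20, 20)
    if (!any(y)) y[1, 1] <- TRUE
    s <- synaptic_contact(nmj_mask(x, cal), nmj_mask(y, cal))
    expect_lte(s[["contact_area_um2"]],
               min(sum(x), sum(y)) * cal^2 + 1e-12)
    expect_gte(s[["overlap_pct"]], 0)
    expect_lte(s[["overlap_pct"]], 100 + 1e-9)
  }
  expect_error(synaptic_contact(nmj_mask(matrix(TRUE, 2, 2), cal),
                                nmj_mask(matrix(TRUE, 3, 3), cal)))
})
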