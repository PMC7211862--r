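# The fixture generator: determinism, analytic truth, recovery and the
# engineered failure modes.

test_that("generation is byte-identical under a fixed seed", {
  sp <- nmj_preset("nominal")
  g1 <- generate_nmj(sp, seed = 1)
  g2 <- generate_nmj(sp, seed = 1)
  expect_identical(g1$stack$voxels, g2$stack$voxels)
  g3 <- generate_nmj(sp, seed = 2)
  expect_false(identical(g1$stack$voxels, g3$stack$voxels))
  # generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_nmj(sp, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("truth metrics are analytically consistent with the spec geometry", {
  # single disc cluster, radius 10 px at 0.1 um/px: area ~ pi um^2
  sp <- nmj_spec(clusters = list(nmj_cluster(c(150, 150), 10)),
                 tree = list(list(from = c(100, 100), to = c(100, 140)),
                             list(from = c(100, 140), to = c(72, 168)),
                             list(from = c(100, 140), to = c(128, 168))),
                 axon = list(from = c(30, 60), to = c(100, 100),
                             width_px = 4),
                 noise_sigma = 0)
  tr <- truth_metrics(sp)
  expect_equal(tr$achr_area_um2, pi, tolerance = 1e-9)     # exact formula
  expect_equal(tr$n_achr_clusters, 1L)
  expect_equal(tr$fragmentation, 0)
  # tree of 3 segments meeting at one node
  expect_equal(tr$n_terminal_branches, 3L)
  expect_equal(tr$n_branch_points, 1L)
  expect_equal(tr$total_branch_length_um, (40 + 2 * 28 * sqrt(2)) * 0.1)
  expect_equal(tr$axon_diameter_um, 0.4)
  # rasterized truth area within the stated discretization bound
  m <- nmj_mask(nmjmetrics:::.render_clusters(sp, FALSE), 0.1)
  expect_lt(abs(sum(m$pixels) * 0.01 - pi), attr(tr, "tol")["achr_area_um2"])
  # identical nerve and AChR geometry would give 100% overlap
  expect_lte(tr$overlap_pct, 100)
})

test_that("the pipeline recovers cluster counts exactly on noise-free fixtures", {
  # 4 clusters, no noise
  sp <- nmj_spec(clusters = list(nmj_cluster(c(120, 120), 11),
                                 nmj_cluster(c(120, 160), 10),
                                 nmj_cluster(c(158, 124), 10),
                                 nmj_cluster(c(162, 165), 12)),
                 tree = list(list(from = c(120, 120), to = c(150, 150))),
                 noise_sigma = 0)
  gen <- generate_nmj(sp, seed = 5)
  rec <- analyze_image(gen$stack, nmj_config())
  expect_equal(rec$n_achr_clusters, 4L)
  # enclosure preset: 5 watershed components, 4 counted clusters
  gen2 <- generate_nmj(nmj_preset("enclosed"), seed = 5)
  achr <- threshold_mask(max_project(gen2$stack, "achr"), "otsu")$mask
  expect_equal(max(watershed_split(achr)$labels), 5L)
  rec2 <- analyze_image(gen2$stack, nmj_config(), axon = gen2$truth$axon)
  expect_equal(rec2$n_achr_clusters, 4L)
  expect_equal(rec2$n_achr_clusters, gen2$truth$record$n_achr_clusters)
})

test_that("extraneous particles outside the endplate change no metric", {
  base <- nmj_preset("nominal")
  base$noise_sigma <- 0
  with_extra <- base
  without <- base
  without$clusters <- Filter(function(x) !x$extraneous, base$clusters)
  r1 <- analyze_image(generate_nmj(with_extra, seed = 3)$stack, nmj_config(),
                      axon = generate_nmj(with_extra, seed = 3)$truth$axon)
  r2 <- analyze_image(generate_nmj(without, seed = 3)$stack, nmj_config(),
                      axon = generate_nmj(without, seed = 3)$truth$axon)
  for (v in nmj_variable_names())
    expect_equal(r1[[v]], r2[[v]], info = v)
})

test_that("doubling a cluster radius quadruples its recovered area (monotone response)", {
  mk <- function(r) nmj_spec(clusters = list(nmj_cluster(c(150, 150), r)),
                             tree = list(list(from = c(80, 80),
                                              to = c(80, 120))),
                             noise_sigma = 0)
  a1 <- analyze_image(generate_nmj(mk(10), seed = 1)$stack,
                      nmj_config())$achr_area_um2
  a2 <- analyze_image(generate_nmj(mk(20), seed = 1)$stack,
                      nmj_config())$achr_area_um2
  expect_lt(abs(a2 / a1 - 4), 4 * 0.04)
})

test_that("failure-case fixtures trip the QC exactly as designed", {
  web <- generate_failure_case("spiderweb", seed = 2)
  achr <- threshold_mask(max_project(web$stack, "achr"), "otsu")$mask
  fp <- build_footprint(achr)
  qc <- check_segmentation(watershed_split(achr), fp)
  expect_true(qc$aberrant)
  expect_gt(qc$particle_count, 50)
  lq <- generate_failure_case("low_quality", seed = 2)
  rec <- analyze_image(lq$stack, nmj_config())
  expect_true(any(grepl("aberrant_segmentation|threshold", rec$qc_flags)))
  # nominal control is NOT flagged
  nom <- generate_nmj(nmj_preset("nominal"), seed = 2)
  recn <- analyze_image(nom$stack, nmj_config(), axon = nom$truth$axon)
  expect_false(any(grepl("aberrant", recn$qc_flags)))
})

test_that("write_fixture emits a calibrated TIFF the loader understands", {
  tmp <- withr::local_tempdir()
  gen <- generate_nmj(nmj_preset("nominal"), seed = 6)
  path <- write_fixture(gen, tmp, "fix")
  stk <- load_stack(path)
  expect_equal(dim(stk$voxels), dim(gen$stack$voxels))
  expect_equal(stk$calibration_um_per_px, 0.1, tolerance = 1e-6)
  expect_equal(stk$voxels, gen$stack$voxels)
  tj <- jsonlite::read_json(file.path(tmp, "fix_truth.json"))
  expect_equal(tj$n_achr_clusters, gen$truth$record$n_achr_clusters)
})
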