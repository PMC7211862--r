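# TIFF I/O, projection and the curated results table.

test_that("TIFF write/read round-trips shape, values, layout and calibration", {
  tmp <- withr::local_tempdir()
  set.seed(42)
  pages <- lapply(1:6, function(i) matrix(sample(0:255, 20 * 15, TRUE), 20, 15))
  path <- file.path(tmp, "s.tif")
  write_tiff(pages, path, calibration_um_per_px = 0.1, channels = 2L,
             slices = 3L)
  tf <- read_tiff(path)
  expect_length(tf$pages, 6L)
  expect_equal(tf$channels, 2L)
  expect_equal(tf$slices, 3L)
  expect_equal(tf$calibration_um_per_px, 0.1, tolerance = 1e-6)
  for (i in 1:6) expect_equal(tf$pages[[i]], pages[[i]],
                              ignore_attr = TRUE)
  # 16-bit
  p16 <- matrix(seq(0, 65535, length.out = 50), 10, 5)
  write_tiff(list(round(p16)), file.path(tmp, "s16.tif"), 0.2, bits = 16L)
  expect_equal(read_tiff(file.path(tmp, "s16.tif"))$pages[[1]],
               round(p16), ignore_attr = TRUE)
})

test_that("files written here parse identically under Python tifffile", {
  tmp <- withr::local_tempdir()
  pages <- list(matrix(0:149, 15, 10), matrix(rev(0:149), 15, 10))
  path <- file.path(tmp, "x.tif")
  write_tiff(pages, path, 0.25, channels = 2L, slices = 1L)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import tifffile,sys;",
    "t=tifffile.TiffFile('", path, "');a=t.asarray();",
    "print(a.shape[0],a.shape[1],a.shape[2],int(a.sum()),",
    "t.imagej_metadata['channels'])"))),
    stdout = TRUE, stderr = TRUE))
  vals <- strsplit(trimws(out[length(out)]), " ")[[1]]
  expect_equal(as.integer(vals),
               c(2L, 15L, 10L, sum(0:149) * 2L, 2L))
})

test_that("load_stack enforces the calibration precedence contract", {
  tmp <- withr::local_tempdir()
  pages <- list(matrix(1, 8, 8), matrix(2, 8, 8))
  # metadata calibration wins
  write_tiff(pages, file.path(tmp, "a.tif"), 0.1, channels = 2L)
  stk <- load_stack(file.path(tmp, "a.tif"))
  expect_s3_class(stk, "nmj_zstack")
  expect_equal(stk$calibration_um_per_px, 0.1, tolerance = 1e-6)
  # config fallback when the file has none
  write_tiff(pages, file.path(tmp, "b.tif"), NA, channels = 2L)
  stk2 <- load_stack(file.path(tmp, "b.tif"), calibration_um_per_px = 0.2)
  expect_equal(stk2$calibration_um_per_px, 0.2)
  # neither -> configuration error naming the image
  expect_error(load_stack(file.path(tmp, "b.tif")), "b\\.tif")
  # bad channel index
  expect_error(load_stack(file.path(tmp, "a.tif"), c(nerve = 1L, achr = 7L)),
               "out of bounds")
  expect_error(load_stack(file.path(tmp, "missing.tif")), "no such file")
})

test_that("max_project is a pointwise maximum with the expected identities", {
  sl <- matrix(runif(100, 0, 50), 10, 10)
  # constant stack: idempotent
  vox0 <- array(0, c(1, 3, 10, 10))
  for (z in 1:3) vox0[1, z, , ] <- sl
  stk <- nmj_zstack(vox0, 0.1, "achr")
  expect_equal(max_project(stk, "achr")$pixels, sl)
  # union property: distinct bright pixels across slices all survive
  vox <- array(0, c(1, 3, 10, 10))
  vox[1, 1, 2, 2] <- 100; vox[1, 2, 5, 7] <- 120; vox[1, 3, 9, 9] <- 90
  mp <- max_project(nmj_zstack(vox, 0.1, "nerve"), "nerve")
  expect_equal(mp$pixels[2, 2], 100)
  expect_equal(mp$pixels[5, 7], 120)
  expect_equal(mp$pixels[9, 9], 90)
  # pointwise >= every slice; single slice is the identity
  set.seed(1)
  vox2 <- array(runif(2 * 4 * 6 * 6, 0, 10), c(2, 4, 6, 6))
  stk2 <- nmj_zstack(vox2, 0.1, c("nerve", "achr"))
  mp2 <- max_project(stk2, "achr")
  for (z in 1:4) expect_true(all(mp2$pixels >= vox2[2, z, , ] - 1e-12))
  one <- nmj_zstack(array(vox2[1, 1, , ], c(1, 1, 6, 6)), 0.1, "nerve")
  expect_equal(max_project(one, "nerve")$pixels, vox2[1, 1, , ])
  expect_error(max_project(one, "achr"), "not present")
})

test_that("results CSV carries exactly the 19 metric columns plus provenance", {
  gen <- generate_nmj(nmj_preset("enclosed"), seed = 3)
  rec <- analyze_image(gen$stack, nmj_config(), axon = gen$truth$axon,
                       image_id = "fix1")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_results(list(rec), tmp)
  tab <- utils::read.csv(tmp, check.names = FALSE)
  expect_equal(nrow(tab), 1L)
  expect_identical(names(tab)[1:19], nmj_variable_names())
  expect_length(nmj_variable_names(), 19L)
  expect_true(all(c("image_id", "image_width_px", "image_height_px",
                    "calibration_um_per_px", "threshold_nerve",
                    "threshold_achr", "qc_flags") %in% names(tab)))
  # row count equals record count
  many <- rep(list(rec), 240L)
  write_results(many, tmp)
  expect_equal(nrow(utils::read.csv(tmp)), 240L)
  # schema is stable across runs
  write_results(list(rec), tmp)
  expect_identical(names(utils::read.csv(tmp, check.names = FALSE)),
                   c(nmj_variable_names(),
                     names(tab)[20:length(names(tab))]))
})

test_that("aberrant records leave cluster cells empty but keep the rest", {
  gen <- generate_failure_case("spiderweb", seed = 5)
  rec <- analyze_image(gen$stack, nmj_config(), image_id = "web")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_results(list(rec), tmp)
  raw <- utils::read.csv(tmp, check.names = FALSE)
  for (v in c("n_achr_clusters", "average_cluster_area_um2", "fragmentation"))
    expect_true(is.na(raw[[v]]))
  for (v in c("achr_area_um2", "achr_perimeter_um", "endplate_area_um2",
              "endplate_diameter_um", "nerve_terminal_area_um2",
              "compactness_pct", "overlap_pct"))
    expect_false(is.na(raw[[v]]))
})
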