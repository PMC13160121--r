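noise_free <- function(background = 0)
  imaging_params(background = background, noise = NULL)

test_that("a single nucleus renders as a Gaussian blob at its position", {
  tab <- toy_table(matrix(c(0, 0, 0), 1), intensities = list(M = 500))
  img <- rasterize_aggregate(tab, noise_free())
  arr <- img$data$M
  peak <- which(arr == max(arr), arr.ind = TRUE)[1, ]
  vox <- img$voxel_size
  peak_um <- c(x = (peak[[3]] - 0.5) * vox[["x"]],
               y = (peak[[2]] - 0.5) * vox[["y"]],
               z = (peak[[1]] - 0.5) * vox[["z"]])
  truth_um <- c(0, 0, 0) + img$offset
  expect_true(all(abs(peak_um - truth_um) <= vox[c("x", "y", "z")]))
})

test_that("rasterization is linear in the marker intensity", {
  pos <- matrix(c(0, 0, 0), 1)
  i1 <- rasterize_aggregate(toy_table(pos, intensities = list(M = 300)),
                            noise_free(background = 5))
  i2 <- rasterize_aggregate(toy_table(pos, intensities = list(M = 600)),
                            noise_free(background = 5))
  s1 <- sum(i1$data$M - 5)
  s2 <- sum(i2$data$M - 5)
  expect_equal(s2 / s1, 2, tolerance = 1e-10)
})

test_that("volume containment and voxel validity are enforced", {
  tab <- toy_table(runif_ball_fixture(30, 40), intensities = list(M = rep(1, 30)))
  expect_error(rasterize_aggregate(tab, imaging_params(image_shape = c(5, 5, 5),
                                                       noise = NULL)),
               "exceeds image volume")
  expect_error(imaging_params(voxel_size = c(z = 0, y = 1, x = 1)), "positive")
})

test_that("TIFF round trip preserves intensities and metadata", {
  tab <- toy_table(matrix(rnorm(15, sd = 10), 5), types = rep(c("A", "B"), c(2, 3)),
                   intensities = list(M = c(10, 20, 30, 40, 50)))
  img <- rasterize_aggregate(tab, noise_free(background = 2))
  tf <- file.path(tempdir(), "roundtrip.tif")
  write_aggregate_tiff(img, tf)
  back <- read_aggregate_tiff(tf)
  expect_identical(back$channels, img$channels)
  expect_equal(back$voxel_size, img$voxel_size)
  scale <- max(sapply(img$data, max))
  expect_lt(max(abs(back$data$M - img$data$M)), scale / 65000)
  expect_lt(max(abs(back$data$DAPI - img$data$DAPI)), scale / 65000)
})

test_that("detection: empty images, resolvable pairs, and kernel collapse", {
  blank <- rasterize_aggregate(toy_table(matrix(0, 1, 3),
                                         intensities = list(M = 1)),
                               noise_free())
  blank$data$DAPI[] <- 0
  expect_equal(nrow(detect_nuclei(blank)), 0)

  # two blobs 6 sigma apart -> exactly two detections
  sep <- 6 * 3
  two <- toy_table(rbind(c(-sep / 2, 0, 0), c(sep / 2, 0, 0)),
                   intensities = list(M = c(1, 1)))
  img <- rasterize_aggregate(two, noise_free())
  expect_equal(nrow(detect_nuclei(img, sigma = 3, min_separation = 6)), 2)

  expect_error(detect_nuclei(img, sigma = 0.5), "collapses")
  expect_error(detect_nuclei(img, nuclear_channel = "nope"), "not present")
})

test_that("rasterize-then-detect recovers well-separated nuclei", {
  p <- synthetic_params(n_cells = 50, radius = 45, pattern = "mixed",
                        min_spacing = 10, seed = 1)
  a <- generate_aggregate(p)
  img <- rasterize_aggregate(a, imaging_params(), seed = 101)
  det <- detect_nuclei(img, sigma = 3, min_separation = 7)
  truth <- sweep(nucleus_positions(a), 2, img$offset, "+")
  m <- match_detections(truth, det)
  expect_gte(mean(m$nn_dist <= 2), 0.95)       # 1 voxel (z) in um
  expect_lte(nrow(det) - 50, 2)                # at most 2 spurious
})

test_that("intensity measurement: constant fields, empty inputs, apertures", {
  img <- new_image_fixture(value = 7)
  pos <- cbind(x = c(10, 20), y = c(10, 12), z = c(6, 8))
  tab <- measure_intensities(img, pos, aperture_radius = 3,
                             background_quantile = NULL)
  expect_equal(unname(tab$M), c(7, 7))

  empty <- measure_intensities(img, pos[0, , drop = FALSE], aperture_radius = 3)
  expect_s3_class(empty, "aggregate_table")
  expect_equal(nrow(empty), 0)

  expect_error(measure_intensities(img, pos, aperture_radius = 0.5),
               "aperture_radius")
})

test_that("measured marker intensities preserve the generator rank order", {
  a <- generate_aggregate(synthetic_params(n_cells = 40, radius = 45,
                                           min_spacing = 10, seed = 8))
  img <- rasterize_aggregate(a, noise_free())
  truth <- sweep(nucleus_positions(a), 2, img$offset, "+")
  tab <- measure_intensities(img, truth, aperture_radius = 3)
  expect_gte(cor(tab$mCherry, a$mCherry, method = "spearman"), 0.95)
})

test_that("marker calling separates clean modes and flags degenerate input", {
  mm <- marker_model(channels = "M", meanlog_a = 8, meanlog_b = 3, sdlog = 0.4)
  a <- generate_aggregate(synthetic_params(n_cells = 200, marker_model = mm,
                                           seed = 13))
  for (meth in c("otsu", "gmm2")) {
    called <- call_marker_positive(a, "M", method = meth)
    expect_identical(as.logical(called$call_M), a$true_type == "A",
                     info = meth)
    expect_false(attr(called, "call_info")$M$degenerate)
  }

  const <- toy_table(matrix(rnorm(30), 10), intensities = list(M = rep(4, 10)))
  expect_warning(cc <- call_marker_positive(const, "M"), "degenerate")
  expect_true(all(cc$call_M == 0))
  expect_true(attr(cc, "call_info")$M$degenerate)

  expect_error(call_marker_positive(a, "M", method = "fixed"), "threshold")
  expect_error(call_marker_positive(a, "nope"), "not present")
})

test_that("gmm2 boundary is close to the error-minimizing threshold", {
  mm <- marker_model(channels = "M", meanlog_a = 6, meanlog_b = 4.5, sdlog = 0.5)
  a <- generate_aggregate(synthetic_params(n_cells = 400, marker_model = mm,
                                           seed = 17))
  called <- call_marker_positive(a, "M", method = "gmm2")
  thr <- attr(called, "call_info")$M$threshold
  # oracle: grid search over log thresholds against generator truth
  lx <- log(a$M)
  grid <- seq(min(lx), max(lx), length.out = 2000)
  err <- vapply(grid, function(t)
    sum((lx > t) != (a$true_type == "A")), 0)
  opt <- grid[which.min(err)]
  expect_lt(abs(thr - opt), 0.1 * abs(opt))
})

test_that("marker calls are invariant to a global intensity rescaling", {
  a <- generate_aggregate(synthetic_params(n_cells = 150, seed = 19))
  for (meth in c("otsu", "gmm2")) {
    c1 <- call_marker_positive(a, "mCherry", method = meth)
    b <- a
    b$mCherry <- b$mCherry * 7.3
    c2 <- call_marker_positive(b, "mCherry", method = meth)
    expect_identical(c1$call_mCherry, c2$call_mCherry, info = meth)
  }
})

test_that("full round trip recovers most marker calls at 3-SD separation", {
  a <- generate_aggregate(synthetic_params(n_cells = 50, radius = 45,
                                           min_spacing = 10, seed = 2))
  img <- rasterize_aggregate(a, imaging_params(), seed = 102)
  det <- detect_nuclei(img, sigma = 3, min_separation = 7)
  tab <- call_marker_positive(
    measure_intensities(img, det, aperture_radius = 3), "mCherry")
  m <- match_detections(sweep(nucleus_positions(a), 2, img$offset, "+"), det)
  acc <- mean((tab$call_mCherry == 1) ==
                (a$true_type[m$nearest_truth] == "A"))
  expect_gte(acc, 0.85)
})

test_that("MIP projection yields a 2D image usable downstream", {
  a <- generate_aggregate(synthetic_params(n_cells = 30, radius = 40,
                                           min_spacing = 10, seed = 6))
  img <- rasterize_aggregate(a, imaging_params(project_mip = TRUE), seed = 3)
  expect_s3_class(img$mip, "aggregate_image")
  expect_length(dim(img$mip$data$DAPI), 2)
  det <- detect_nuclei(img$mip, sigma = 3, min_separation = 7)
  expect_identical(colnames(det), c("x", "y"))
  tab <- measure_intensities(img$mip, det, aperture_radius = 3)
  expect_false("z" %in% names(tab))
})
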