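# per-ROI thresholding, clustering segmentation and the SAC merge workflow

test_that("absolute threshold keeps exactly the voxels at or above the cut-off", {
  vol <- vol3(c(rep(3, 10), rep(1, 54)))
  rois <- roi_over(1:10)
  seg <- segment_threshold_abs(vol, rois)
  expect_equal(sum(seg$mask), 10)

  vol2 <- vol3(rep(2, 64))
  expect_warning(seg2 <- segment_threshold_abs(vol2, roi_over(1:10)),
                 "empty")
  expect_equal(sum(seg2$mask), 0)

  set.seed(88)
  vals <- runif(64, 0, 5)
  seg3 <- segment_threshold_abs(vol3(vals), roi_over(1:40))
  expect_equal(sum(seg3$mask), sum(vals[1:40] >= 2.5))  # exhaustive scan
})

test_that("relative threshold adapts per ROI and includes the boundary", {
  vals <- rep(1, 64)
  vals[1:5] <- c(10, 4.1, 4.0999, 5, 2)   # ROI 1: max 10 -> cut-off 4.1
  vals[33:36] <- c(20, 8.2, 8.1, 9)       # ROI 2: max 20 -> cut-off 8.2
  lab <- array(0L, c(4, 4, 4)); lab[1:5] <- 1L; lab[33:36] <- 2L
  seg <- segment_threshold_rel(vol3(vals), roi_set(lab))
  expect_true(seg$mask[2])    # 4.1 >= 4.1: boundary-inclusive
  expect_false(seg$mask[3])   # 4.0999 < 4.1
  expect_false(seg$mask[35])  # 8.1 < 8.2 despite exceeding ROI 1's cut-off
  expect_equal(seg$roi_info$threshold, c(4.1, 8.2))
  # per-ROI brute force
  expect_equal(sum(seg$mask[1:5]), sum(vals[1:5] >= 4.1))
  expect_equal(sum(seg$mask[33:36]), sum(vals[33:36] >= 8.2))

  # uniform ROI: every voxel equals fraction * max <= max, all kept
  segu <- segment_threshold_rel(vol3(rep(4, 64)), roi_over(1:12))
  expect_equal(sum(segu$mask), 12)
})

test_that("thresholded masks are nested as the cut-off rises", {
  set.seed(14)
  vol <- vol3(runif(64, 0, 6))
  rois <- roi_over(sample(64, 30))
  m1 <- segment_threshold_abs(vol, rois, threshold = 1.5)$mask
  m2 <- suppressWarnings(segment_threshold_abs(vol, rois, threshold = 3.5)$mask)
  expect_true(all(m2[m1 == FALSE] == FALSE))  # mask(t2) subset of mask(t1)
  r1 <- segment_threshold_rel(vol, rois, fraction = 0.3)$mask
  r2 <- segment_threshold_rel(vol, rois, fraction = 0.7)$mask
  expect_true(all(!r2[!r1]))
})

test_that("no voxel outside an ROI is ever labeled lesion", {
  set.seed(3)
  vol <- vol3(runif(64, 0, 10))
  idx <- sample(64, 20)
  rois <- roi_over(idx)
  for (method in segmentation_methods()) {
    seg <- suppressWarnings(segment(vol, rois, method = method))
    expect_true(all(which(seg$mask) %in% idx), info = method)
  }
})

test_that("misaligned grids are refused", {
  vol <- vol3(rep(1, 64), spacing = c(4, 4, 4))
  rois <- roi_over(1:10, spacing = c(2, 2, 2))
  expect_error(segment_threshold_abs(vol, rois),
               class = "petsac_alignment_error")
})

test_that("2-class clustering takes the highest-mean class as lesion", {
  vol <- vol3(c(rep(1, 3), rep(9, 3), rep(0.5, 58)))
  rois <- roi_over(1:6)
  km <- segment_clustering(vol, rois, base = "kmeans")
  expect_equal(which(km$mask), 4:6)
  # the mixture needs 5 values per class
  vol_b <- vol3(c(rep(1, 5), rep(9, 5), rep(0.5, 54)))
  by <- suppressWarnings(segment_clustering(vol_b, roi_over(1:10),
                                            base = "bayesian"))
  expect_equal(which(by$mask), 6:10)

  # well-separated bimodal ROI: k-means and MAP agree
  set.seed(61)
  vals <- c(rnorm(100, 1, 0.1), rnorm(100, 8, 0.3), rep(0, 56))
  v <- vol3(abs(vals), shape = c(8, 8, 4))
  rois2 <- roi_over(1:200, shape = c(8, 8, 4))
  mk <- segment_clustering(v, rois2, base = "kmeans")
  mb <- segment_clustering(v, rois2, base = "bayesian")
  expect_identical(mk$mask, mb$mask)
})

test_that("high-contrast SAC merges the border into the lesion", {
  ph <- sphere_phantom(suv = 15, radius = 14, background = 0.05,
                       shape = c(24, 24, 24), spacing = c(4, 4, 4),
                       psf_fwhm = 7, noise_sd = 0.02, seed = 5)
  sac <- segment_sac(ph$volume, ph$rois, base = "kmeans")
  expect_equal(sac$roi_info$branch, "merge_two_higher")
  expect_gte(sac$roi_info$coef, 0.94)
  km2 <- segment_clustering(ph$volume, ph$rois, base = "kmeans", k = 2)
  # border class joins the lesion: SAC mask contains the 2-class mask
  expect_true(all(km2$mask[!sac$mask] == FALSE))
  expect_gt(sum(sac$mask), 0)
})

test_that("low-contrast SAC merges the border into the background", {
  ph <- sphere_phantom(suv = 4, radius = 14, background = 2,
                       shape = c(24, 24, 24), spacing = c(4, 4, 4),
                       psf_fwhm = 7, noise_sd = 0.05, seed = 6)
  sac <- segment_sac(ph$volume, ph$rois, base = "kmeans")
  expect_equal(sac$roi_info$branch, "merge_two_lower")
  expect_lt(sac$roi_info$coef, 0.90)
  # lesion = class 3 only, hence a subset of the classes {2, 3} selection
  vals <- ph$volume$values[ph$rois$labels == 1]
  m3 <- kmeans_1d(vals, 3)
  idx <- which(ph$rois$labels == 1)
  merged_higher <- idx[m3$assignment >= 2]
  expect_true(all(which(sac$mask) %in% merged_higher))
})

test_that("degenerate ROIs fall back to the relative threshold with a warning", {
  vol <- vol3(rep(5, 64))
  rois <- roi_over(1:20)
  expect_warning(seg <- segment_sac(vol, rois, base = "kmeans"),
                 "falling back")
  expect_equal(seg$roi_info$branch, "fallback_rel")
  expect_equal(sum(seg$mask), 20)  # uniform: all at 41% of max
})

test_that("segmentation is deterministic on repeated runs", {
  ph <- sphere_phantom(suv = 6, radius = 12, psf_fwhm = 7, noise_sd = 0.1,
                       seed = 19)
  for (method in c("rel41", "kmeans", "sac-bayes")) {
    a <- suppressWarnings(segment(ph$volume, ph$rois, method = method))
    b <- suppressWarnings(segment(ph$volume, ph$rois, method = method))
    expect_identical(a$mask, b$mask, info = method)
    expect_identical(a$roi_info, b$roi_info, info = method)
  }
})
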