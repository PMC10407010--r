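# phantom generation, observer perturbation and cohort sampling

test_that("a clean phantom is two-valued with exact ground truth", {
  ph <- sphere_phantom(suv = 6, radius = 12, psf_fwhm = 0, noise_sd = 0)
  expect_setequal(unique(as.vector(ph$volume$values)), c(1, 6))
  expect_identical(ph$truth$labels > 0,
                   array(ph$volume$values == 6, dim(ph$volume$values)))
  # ROI fully contains its lesion with a margin
  expect_true(all(ph$rois$labels[ph$truth$labels > 0] == 1))
  expect_gt(sum(ph$rois$labels == 1), sum(ph$truth$labels == 1))
})

test_that("generation is reproducible from the seed", {
  a <- sphere_phantom(psf_fwhm = 7, noise_sd = 0.2, seed = 123)
  b <- sphere_phantom(psf_fwhm = 7, noise_sd = 0.2, seed = 123)
  expect_identical(a$volume$values, b$volume$values)
  c_ <- sphere_phantom(psf_fwhm = 7, noise_sd = 0.2, seed = 124)
  expect_false(identical(a$volume$values, c_$volume$values))
})

test_that("ground-truth sphere volume approximates the analytic ball", {
  ph <- sphere_phantom(suv = 5, radius = 12, shape = c(32, 32, 32),
                       spacing = c(2, 2, 2), psf_fwhm = 0, noise_sd = 0)
  expect_equal(mtv(ph$truth$labels > 0, c(2, 2, 2)),
               4 / 3 * pi * 1.2^3, tolerance = 0.03)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(lesions = list(list(center = c(10, 10, 10),
                                                radii = 8, suv = 0.5))),
               class = "petsac_spec_error")  # colder than background
  expect_error(phantom_spec(shape = c(10, 10, 10),
                            lesions = list(list(center = c(2, 2, 2),
                                                radii = 20, suv = 5))),
               class = "petsac_spec_error")  # outside the grid
})

test_that("clean phantoms are segmented exactly by every method family", {
  spec <- phantom_spec(shape = c(28, 28, 28), spacing = c(4, 4, 4),
                       lesions = list(
                         list(center = c(34, 34, 34), radii = 11, suv = 6.5),
                         list(center = c(80, 78, 76), radii = 9, suv = 4.8)),
                       psf_fwhm = 0, noise_sd = 0)
  ph <- generate_phantom(spec)
  gt <- ph$truth$labels > 0
  # any absolute threshold strictly between background and lesion SUV works
  for (thr in c(1.5, 2.5, 4.0)) {
    seg <- segment_threshold_abs(ph$volume, ph$rois, threshold = thr)
    expect_equal(dice(seg$mask, gt), 1, info = paste("thr", thr))
  }
  for (method in c("rel41", "kmeans", "bayes")) {
    seg <- suppressWarnings(segment(ph$volume, ph$rois, method = method))
    expect_equal(dice(seg$mask, gt), 1, info = method)
  }
})

test_that("observer perturbation is seeded, bounded and identity at magnitude 0", {
  ph <- sphere_phantom(psf_fwhm = 0, noise_sd = 0)
  expect_identical(perturb_roi(ph$rois, 0), ph$rois)
  p1 <- perturb_roi(ph$rois, 1, seed = 42)
  p2 <- perturb_roi(ph$rois, 1, seed = 42)
  expect_identical(p1$labels, p2$labels)

  # bounded by one box dilation / erosion of the original
  for (s in c(1, 7, 19)) {
    p <- perturb_roi(ph$rois, 1, seed = s)
    m0 <- ph$rois$labels == 1
    m <- p$labels == 1
    hull <- dilate_mask(m0, 1, 26)
    core <- erode_mask(m0, 1, 26)
    expect_true(all(which(m) %in% which(hull)))
    expect_true(all(which(core) %in% which(m)))
    expect_gte(sum(m), 1)
  }
})

test_that("erosion never removes an ROI entirely", {
  lab <- array(0L, c(6, 6, 6)); lab[3, 3, 3] <- 1L  # single-voxel ROI
  rois <- roi_set(lab)
  for (s in 1:10) {
    p <- perturb_roi(rois, 2, seed = s)
    expect_gte(sum(p$labels == 1), 1)
  }
})

test_that("cohorts are reproducible and respect the sampling ranges", {
  a <- phantom_cohort(3, seed = 77, shape = c(32, 32, 32))
  b <- phantom_cohort(3, seed = 77, shape = c(32, 32, 32))
  expect_identical(lapply(a, function(p) p$volume$values),
                   lapply(b, function(p) p$volume$values))
  expect_identical(lapply(a, function(p) p$obs2$labels),
                   lapply(b, function(p) p$obs2$labels))

  suvs <- unlist(lapply(a, function(p)
    vapply(p$spec$lesions, function(l) l$suv, numeric(1))))
  expect_true(all(suvs >= 4.5 & suvs <= 10.3))
  vols <- unlist(lapply(a, function(p)
    vapply(p$spec$lesions, function(l)
      4 / 3 * pi * prod(rep(l$radii, length.out = 3)) / 1000, numeric(1))))
  expect_true(all(vols >= 1.2 & vols <= 9.8))  # target MTV range, pre-voxelization

  # ROIs of distinct lesions never touch (clearance enforced)
  for (p in a) {
    K <- n_rois(p$rois)
    if (K < 2) next
    for (k in seq_len(K - 1)) {
      mk <- dilate_mask(p$rois$labels == k, 1, 26)
      for (l in seq((k + 1), K))
        expect_equal(sum(mk & p$rois$labels == l), 0)
    }
  }
})

test_that("segmentation difficulty rises monotonically with noise", {
  meds <- vapply(c(0, 0.3, 0.9), function(ns) {
    dc <- vapply(1:6, function(i) {
      ph <- sphere_phantom(suv = 5, radius = 11, shape = c(24, 24, 24),
                           psf_fwhm = 7, noise_sd = ns, seed = 1000 + i)
      seg <- suppressWarnings(segment(ph$volume, ph$rois, method = "kmeans"))
      dice(seg$mask, ph$truth$labels > 0)
    }, numeric(1))
    median(dc)
  }, numeric(1))
  expect_true(all(diff(meds) <= 1e-9))
})
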