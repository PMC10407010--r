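# intensity, geometric and dissemination features, and the feature table

test_that("first-order statistics match direct formulas", {
  vol <- vol3(rep(5, 64))
  f <- intensity_features(vol, roi_over(1:10)$labels == 1)
  expect_equal(unname(f[c("suv_max", "suv_min", "suv_mean")]), c(5, 5, 5))
  expect_equal(unname(f["suv_sd"]), 0)

  v2 <- vol3(c(2, 4, rep(0, 62)))
  m2 <- array(c(TRUE, TRUE, rep(FALSE, 62)), c(4, 4, 4))
  f2 <- intensity_features(v2, m2)
  expect_equal(unname(f2["suv_mean"]), 3)
  expect_equal(unname(f2["suv_max"]), 4)

  set.seed(404)
  vals <- runif(64, 0.1, 12)
  mask <- array(runif(64) < 0.5, c(4, 4, 4))
  x <- vals[mask]
  f3 <- intensity_features(vol3(vals), mask)
  m <- mean(x); m2c <- mean((x - m)^2)
  bins <- pmin(pmax(ceiling(x / max(x) * 64), 1), 64)
  p <- as.numeric(table(bins)) / length(x)
  expect_equal(unname(f3["suv_median"]), median(x))
  expect_equal(unname(f3["suv_sd"]), sd(x))
  expect_equal(unname(f3["suv_range"]), max(x) - min(x))
  expect_equal(unname(f3["suv_rms"]), sqrt(mean(x^2)))
  expect_equal(unname(f3["suv_mad"]), mean(abs(x - m)))
  expect_equal(unname(f3["skewness"]), mean((x - m)^3) / m2c^1.5)
  expect_equal(unname(f3["kurtosis"]), mean((x - m)^4) / m2c^2)
  expect_equal(unname(f3["energy"]), sum(x^2))
  expect_equal(unname(f3["entropy"]), -sum(p * log2(p)))
  expect_equal(unname(f3["uniformity"]), sum(p^2))

  expect_error(intensity_features(vol, array(FALSE, c(4, 4, 4))),
               class = "petsac_empty_error")
})

test_that("SUVpeak is the best 3x3x3 neighborhood mean, border-truncated", {
  expect_equal(suv_peak(vol3(rep(4, 64)), array(TRUE, c(4, 4, 4))), 4)

  v <- array(0, c(5, 5, 5)); v[3, 3, 3] <- 27
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  expect_equal(suv_peak(pet_volume(v), m), 1)  # 27 / 27 neighbors

  set.seed(512)
  for (i in 1:6) {
    vals <- array(runif(7^3, 0, 10), c(7, 7, 7))
    mask <- array(runif(7^3) < 0.3, c(7, 7, 7))
    if (!any(mask)) next
    expect_equal(suv_peak(pet_volume(vals), mask),
                 suv_peak_oracle(vals, mask))
  }
})

test_that("SUVpeak never exceeds SUVmax", {
  set.seed(21)
  for (i in 1:10) {
    vals <- array(runif(6^3, 0, 20), c(6, 6, 6))
    mask <- array(runif(6^3) < 0.4, c(6, 6, 6))
    if (!any(mask)) next
    expect_lte(suv_peak(pet_volume(vals), mask), max(vals[mask]))
  }
})

test_that("MTV is voxel count times voxel volume", {
  m <- array(FALSE, c(3, 3, 3)); m[1:10] <- TRUE
  expect_equal(mtv(m, spacing = c(2, 2, 2)), 0.08)
  expect_equal(mtv(array(FALSE, c(3, 3, 3)), spacing = c(2, 2, 2)), 0)

  # voxelized ball vs analytic volume
  r <- 20; n <- 45
  ax <- (0:(n - 1)) - (n - 1) / 2
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  ball <- array(d2 <= r^2, c(n, n, n))
  expect_equal(mtv(ball, spacing = c(1, 1, 1)),
               4 / 3 * pi * 2^3, tolerance = 0.02)
})

test_that("TLG equals MTV times SUVmean", {
  ph <- sphere_phantom(suv = 6, radius = 12, psf_fwhm = 7, noise_sd = 0.1,
                       seed = 2)
  mask <- ph$truth$labels > 0
  got <- tlg(ph$volume, mask)
  expect_equal(got, mtv(mask, c(4, 4, 4)) * mean(ph$volume$values[mask]),
               tolerance = 1e-12)
  # summation oracle: sum of SUV * voxel volume
  expect_equal(got, sum(ph$volume$values[mask]) * prod(c(4, 4, 4)) / 1000,
               tolerance = 1e-9)
  expect_warning(z <- tlg(ph$volume, array(FALSE, dim(mask))), "empty")
  expect_equal(z, 0)
})

test_that("a voxel cube scores the closed-form cube sphericity", {
  m <- array(FALSE, c(8, 8, 8)); m[2:5, 3:6, 2:5] <- TRUE
  g <- geometric_features(m, spacing = c(2, 2, 2))
  expect_equal(unname(g["surface_area_mm2"]), 6 * 8^2)  # side 8 mm
  expect_equal(unname(g["sphericity"]), (pi / 6)^(1 / 3))
  expect_equal(unname(g["compactness2"]),
               36 * pi * 512^2 / (6 * 64)^3 * 1)
  expect_equal(unname(g["spherical_disproportion"]) * unname(g["sphericity"]),
               1, tolerance = 1e-9)
})

test_that("digital sphere sphericity approaches the 2/3 face-count asymptote", {
  r <- 18; n <- 41
  ax <- (0:(n - 1)) - (n - 1) / 2
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  ball <- array(d2 <= r^2, c(n, n, n))
  g <- geometric_features(ball, spacing = c(1, 1, 1))
  expect_equal(unname(g["sphericity"]), 2 / 3, tolerance = 0.05)
})

test_that("maximum 3D diameter is the farthest surface-voxel pair", {
  m <- array(FALSE, c(4, 2, 2)); m[1, 1, 1] <- TRUE; m[2, 1, 1] <- TRUE
  g <- geometric_features(m, spacing = c(3, 3, 3))
  expect_equal(unname(g["max_diameter_mm"]), 3)

  # single voxel: surface features exist, diameter 0
  s <- array(FALSE, c(3, 3, 3)); s[2, 2, 2] <- TRUE
  gs <- geometric_features(s, spacing = c(4, 4, 4))
  expect_equal(unname(gs["max_diameter_mm"]), 0)
  expect_equal(unname(gs["surface_area_mm2"]), 6 * 16)
})

test_that("dissemination features follow the brute-force pairwise oracle", {
  # single lesion: count 1, all distances zero
  one <- label_lesions(array(c(rep(TRUE, 4), rep(FALSE, 60)), c(4, 4, 4)),
                       spacing = c(4, 4, 4))
  d1 <- dissemination_features(one, vol3(rep(2, 64), spacing = c(4, 4, 4)))
  expect_equal(unname(d1["n_lesions"]), 1)
  expect_true(all(d1[c("dmax_patient_mm", "dmax_bulk_mm",
                       "max_surface_dist_mm", "burden_spread_mm")] == 0))

  # two point lesions 50 mm apart
  m <- array(FALSE, c(60, 5, 5)); m[1, 1, 1] <- TRUE; m[51, 1, 1] <- TRUE
  les <- label_lesions(m, spacing = c(1, 1, 1))
  v <- pet_volume(array(1, c(60, 5, 5)) + m * 4)
  d2 <- dissemination_features(les, v)
  expect_equal(unname(d2["dmax_patient_mm"]), 50)
  expect_equal(unname(d2["dmax_bulk_mm"]), 50)
  expect_equal(unname(d2["n_lesions"]), 2)

  # several seeded blobs vs an exhaustive oracle
  set.seed(86)
  lab <- array(0L, c(16, 16, 16))
  centers <- list(c(3, 3, 3), c(12, 4, 3), c(4, 13, 12), c(13, 13, 4),
                  c(8, 8, 14))
  for (k in seq_along(centers)) {
    cc <- centers[[k]]
    lab[cc[1] + (-1:1), cc[2] + (-1:1), cc[3] + (0:1)] <- k
  }
  les5 <- label_lesions(lab > 0, spacing = c(2, 2, 2))
  vals <- array(1, c(16, 16, 16)); vals[lab > 0] <- 5 + lab[lab > 0]
  d5 <- dissemination_features(les5, pet_volume(vals, spacing = c(2, 2, 2)))
  # oracle: centroid distances by explicit loops
  cents <- t(sapply(seq_len(n_lesions(les5)), function(j) {
    idx <- which(les5$labels == j, arr.ind = TRUE)
    colMeans((idx - 1) * 2)
  }))
  pd <- c()
  for (i in 1:4) for (j in (i + 1):5)
    pd <- c(pd, sqrt(sum((cents[i, ] - cents[j, ])^2)))
  expect_equal(unname(d5["n_lesions"]), 5)
  expect_equal(unname(d5["dmax_patient_mm"]), max(pd))
  expect_equal(unname(d5["mean_centroid_dist_mm"]), mean(pd))
  expect_equal(unname(d5["sd_centroid_dist_mm"]), sd(pd))
})

test_that("dissemination distances are translation-invariant and scale with spacing", {
  base <- array(FALSE, c(12, 12, 12))
  base[2:3, 2:3, 2:3] <- TRUE; base[9:10, 8:9, 7:8] <- TRUE
  shifted <- petsac:::shift3d(base, 1, 1, 1, fill = FALSE)
  v1 <- pet_volume(array(1, dim(base)) + base * 5)
  v1s <- pet_volume(array(1, dim(base)) + shifted * 5)
  d_a <- dissemination_features(label_lesions(base), v1)
  d_b <- dissemination_features(label_lesions(shifted), v1s)
  dist_feats <- c("dmax_patient_mm", "dmax_bulk_mm", "mean_centroid_dist_mm",
                  "max_surface_dist_mm", "burden_spread_mm")
  expect_equal(d_a[dist_feats], d_b[dist_feats], tolerance = 1e-9)

  les2 <- label_lesions(base, spacing = c(2, 2, 2))
  v2 <- pet_volume(v1$values, spacing = c(2, 2, 2))
  d_c <- dissemination_features(les2, v2)
  expect_equal(unname(d_c[dist_feats]), 2 * unname(d_a[dist_feats]),
               tolerance = 1e-9)
})

test_that("the patient table keeps per-lesion and burden scopes consistent", {
  ph <- sphere_phantom(suv = 8, radius = 10, psf_fwhm = 7, noise_sd = 0.1,
                       seed = 9, shape = c(32, 32, 32))
  # add a second lesion far away by painting a second phantom
  spec2 <- phantom_spec(shape = c(32, 32, 32), spacing = c(4, 4, 4),
                        lesions = list(
                          list(center = c(30, 30, 30), radii = 10, suv = 8),
                          list(center = c(90, 90, 90), radii = 14, suv = 5)),
                        psf_fwhm = 7, noise_sd = 0.1, seed = 12)
  ph2 <- generate_phantom(spec2)
  ft <- patient_features(ph2$volume, ph2$truth, "P1", "truth", "gt")
  expect_equal(nrow(ft), 3)  # 2 lesions + total burden
  expect_setequal(names(ft)[-(1:5)], feature_registry())

  burden <- ft[ft$scope == "total_burden", ]
  lesions <- ft[grepl("^lesion_", ft$scope), ]
  expect_equal(burden$mtv_cm3, sum(lesions$mtv_cm3), tolerance = 1e-12)
  expect_equal(burden$suv_max, max(lesions$suv_max), tolerance = 1e-12)
  expect_equal(burden$tlg_cm3, burden$mtv_cm3 * burden$suv_mean,
               tolerance = 1e-9)
  expect_true(all(ft$suv_peak <= ft$suv_max + 1e-12))

  # no cross-lesion leakage: each lesion row equals the lesion quantified alone
  for (j in 1:2) {
    alone <- petsac:::single_region_features(ph2$volume,
                                             ph2$truth$labels == j,
                                             c(4, 4, 4))
    row <- lesions[lesions$lesion == j, names(alone)]
    expect_equal(unlist(row), alone, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("representative-lesion selection maximizes the criterion with MTV tie-breaks", {
  tab <- data.frame(scope = c("lesion_1", "lesion_2", "lesion_3",
                              "total_burden"),
                    lesion = c(1L, 2L, 3L, NA),
                    tlg_cm3 = c(3, 9, 1, 13),
                    suv_max = c(7, 5, 7, 7),
                    mtv_cm3 = c(1, 3, 2, 6))
  expect_equal(select_representative(tab, "highest_TLG"), 2L)
  # SUVmax ties between lesions 1 and 3: larger MTV wins
  expect_equal(select_representative(tab, "highest_SUVmax"), 3L)

  single <- tab[c(1, 4), ]
  expect_equal(select_representative(single, "highest_TLG"), 1L)
  expect_equal(select_representative(single, "highest_SUVmax"), 1L)

  # sort-based oracle on a seeded table
  set.seed(65)
  n <- 8
  tab2 <- data.frame(scope = paste0("lesion_", 1:n), lesion = 1:n,
                     tlg_cm3 = sample(c(4, 9), n, replace = TRUE),
                     suv_max = sample(c(5, 8), n, replace = TRUE),
                     mtv_cm3 = runif(n, 1, 5))
  ord <- order(-tab2$suv_max, -tab2$mtv_cm3, tab2$lesion)
  expect_equal(select_representative(tab2, "highest_SUVmax"),
               tab2$lesion[ord[1]])
  expect_error(select_representative(tab[4, ], "highest_TLG"),
               class = "petsac_empty_error")
})
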