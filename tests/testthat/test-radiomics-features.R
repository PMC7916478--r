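test_that("discretization bins in-mask intensities into contiguous levels", {
  vals <- array(c(0, 1, 2, 3), c(4, 1, 1))
  msk <- array(TRUE, c(4, 1, 1))
  d <- discretize(vals, msk, 4)
  expect_equal(as.vector(d$levels), 1:4)
  expect_equal(d$n_levels, 4L)

  dc <- discretize(array(7, c(3, 3, 1)), array(TRUE, c(3, 3, 1)), 8)
  expect_equal(dc$n_levels, 1L)
  expect_true(all(dc$levels[dc$mask] == 1L))

  expect_error(discretize(vals, array(FALSE, c(4, 1, 1)), 4), "empty")
  expect_error(discretize(vals, msk, 1), "n_bins")

  # uniform values occupy bins evenly
  set.seed(3)
  n <- 1e5
  u <- array(runif(n), c(n, 1, 1))
  du <- discretize(u, array(TRUE, c(n, 1, 1)), 32)
  counts <- tabulate(du$levels[du$mask], 32)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("first-order features match hand computations", {
  fo <- first_order_features(array(c(1, 2, 3, 4), c(4, 1, 1)),
                             array(TRUE, c(4, 1, 1)))
  expect_equal(unname(fo["Mean"]), 2.5)
  expect_equal(unname(fo["Median"]), 2.5)

  # constant region: location features equal the constant, skewness undefined
  fc <- first_order_features(array(3, c(3, 3, 1)), array(TRUE, c(3, 3, 1)))
  expect_equal(unname(fc[c("Mean", "Median", "10Percentile", "90Percentile")]),
               rep(3, 4))
  expect_true(is.na(fc["Skewness"]))
  expect_false(any(is.nan(fc)))

  # uniformity via 4 equal-width bins over [1, 4]
  fu <- first_order_features(array(c(1, 1, 2, 2, 4, 4), c(6, 1, 1)),
                             array(TRUE, c(6, 1, 1)), n_bins = 4)
  expect_equal(unname(fu["Uniformity"]), 1 / 3)

  # mask-preserving permutation leaves Mean/Median unchanged
  set.seed(4)
  x <- rnorm(24)
  m <- array(TRUE, c(4, 3, 2))
  f1 <- first_order_features(array(x, c(4, 3, 2)), m)
  f2 <- first_order_features(array(sample(x), c(4, 3, 2)), m)
  expect_equal(f1["Mean"], f2["Mean"])
  expect_equal(f1["Median"], f2["Median"])
})

test_that("shape features respect voxel geometry and axis ordering", {
  s1 <- shape_features(array(TRUE, c(1, 1, 1)), c(1, 1, 1))
  expect_equal(unname(s1["VoxelVolume"]), 1)

  s8 <- shape_features(array(TRUE, c(2, 2, 2)), c(1, 1, 1))
  expect_equal(unname(s8["VoxelVolume"]), 8)
  expect_equal(unname(s8["SurfaceArea"]), 24)
  expect_equal(unname(s8["Maximum3DDiameter"]), sqrt(3))

  box <- shape_features(array(TRUE, c(10, 4, 2)), c(1, 1, 1))
  expect_gte(box[["MajorAxisLength"]], box[["MinorAxisLength"]])
  expect_gte(box[["MinorAxisLength"]], box[["LeastAxisLength"]])
  # PCA oracle: eigenvalues of the coordinate covariance
  idx <- which(array(TRUE, c(10, 4, 2)), arr.ind = TRUE)
  ev <- sort(eigen(stats::cov(idx) * (nrow(idx) - 1) / nrow(idx))$values,
             decreasing = TRUE)
  expect_equal(unname(box["MajorAxisLength"]), 4 * sqrt(ev[1]),
               tolerance = 1e-10)

  # anisotropic spacing scales the volume
  sv <- shape_features(array(TRUE, c(2, 2, 2)), c(1, 2, 5))
  expect_equal(unname(sv["VoxelVolume"]), 8 * 10)
})

test_that("the extractor inventory follows the configuration and is reproducible", {
  prof <- scanner_profile(c(1.5, 1.5), 3, 0.1, 0.02)
  shp <- list(fov_mm = c(36, 36, 21), semi_axes_mm = c(8, 7, 5),
              edema_scale = 1.3)
  v <- generate_tumor_volume(prof, shp, seed = 12)
  cfg_on <- filter_bank_config(log_sigmas_mm = 3, wavelet = TRUE, n_bins = 8)
  cfg_off <- filter_bank_config(log_sigmas_mm = 3, wavelet = FALSE, n_bins = 8)
  masks <- list(T1Gd = v$t1_mask, T2 = v$t2_mask)
  f_on <- extract_features(v$t1, v$t2, masks, cfg_on)
  f_off <- extract_features(v$t1, v$t2, masks, cfg_off)

  man <- attr(f_on, "manifest")
  expect_true(all(c("id", "modality", "filter", "class", "defined") %in%
                    names(man)))
  per_image <- sum(man$modality == "T1" & man$filter == "original" &
                     man$class != "shape")
  expect_equal(length(f_on) - length(f_off), 2 * 8 * per_image)

  # feature ids follow the naming grammar
  expect_true(all(grepl("^(T1|T2)_(original|log\\.sigma\\..*|wavelet\\.[LH]{3})_",
                        names(f_on))))
  expect_true(any(grepl("glszm_LargeAreaLowGrayLevelEmphasis", names(f_on))))

  # identical patients give identical vectors
  f_again <- extract_features(v$t1, v$t2, masks, cfg_on)
  expect_identical(unclass(f_on), unclass(f_again))

  # undefined features are flagged, never dropped
  expect_equal(nrow(man), length(f_on))
  expect_identical(man$defined, unname(is.finite(f_on)))

  expect_gt(feature_inventory_size(filter_bank_config()), 1000)
})
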