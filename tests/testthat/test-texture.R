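test_that("worked texture-matrix examples evaluate exactly", {
  # horizontal pairs on a 2x2 checker: symmetric GLCM mass at (1,2)/(2,1)
  arr <- array(rbind(c(1, 2), c(1, 2)), c(2, 2, 1))
  d <- as_dimg(array(as.integer(arr), dim(arr)), array(TRUE, dim(arr)), 2L)
  g <- gliomix:::glcm_matrix(d$levels, 2L, rbind(c(0, 1, 0)))
  p <- g[, , 1] / sum(g[, , 1])
  expect_equal(p, rbind(c(0, 0.5), c(0.5, 0)))
  f <- gliomix:::glcm_features_one(g[, , 1])
  expect_equal(unname(f["Contrast"]), 1)
  expect_equal(unname(f["DifferenceAverage"]), 1)

  # 3x3 zone example: zones (1,2), (2,3), (3,4)
  m <- rbind(c(1, 1, 2), c(2, 2, 3), c(3, 3, 3))
  d2 <- as_dimg(array(as.integer(m), c(3, 3, 1)), array(TRUE, c(3, 3, 1)), 3L)
  z <- gliomix:::glszm_matrix(d2$levels, 3L)
  expect_equal(sum(z), 3)                       # Nz = 3
  expect_equal(which(z[1, ] > 0), 2L)
  expect_equal(which(z[2, ] > 0), 3L)
  expect_equal(which(z[3, ] > 0), 4L)
  zf <- glszm_features(z, 9)
  expect_equal(unname(zf["LargeAreaLowGrayLevelEmphasis"]),
               (4 / 1 + 9 / 4 + 16 / 9) / 3, tolerance = 1e-12)

  # constant cube: one zone of 27, all GLCM mass on (1,1), zero contrast
  dc <- discretize(array(1.5, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 4)
  mats <- texture_matrices(dc)
  expect_equal(sum(mats$glszm), 1)
  expect_equal(mats$glszm[1, 27], 1)
  expect_true(all(mats$glcm[1, 1, ] == apply(mats$glcm, 3, sum)))
  tf <- texture_features(mats)
  expect_equal(unname(tf["glcm_Contrast"]), 0)
  # a constant single-voxel region has exactly one dependence state
  d1 <- discretize(array(2, c(1, 1, 1)), array(TRUE, c(1, 1, 1)), 4)
  expect_equal(unname(texture_features(texture_matrices(d1))["gldm_DependenceEntropy"]),
               0)
})

test_that("texture matrices satisfy their structural invariants", {
  r <- random_dimg(101, dims = c(6, 6, 4), ng = 5)
  dimg <- as_dimg(r$lev, r$mask, r$ng)
  mats <- texture_matrices(dimg)

  # GLCM symmetry and normalisation per direction
  for (k in seq_len(dim(mats$glcm)[3])) {
    P <- mats$glcm[, , k]
    expect_equal(P, t(P))
    if (sum(P) > 0) expect_equal(sum(P / sum(P)), 1)
  }
  # GLSZM zone sizes sum to the in-mask voxel count
  expect_equal(sum(mats$glszm %*% seq_len(ncol(mats$glszm))), sum(r$mask))
  # GLDM rows cover every in-mask voxel once
  expect_equal(sum(mats$gldm), sum(r$mask))
  # GLRLM runs cover every voxel once per direction
  for (k in seq_len(dim(mats$glrlm)[3]))
    expect_equal(sum(mats$glrlm[, , k] %*% seq_len(ncol(mats$glrlm))),
                 sum(r$mask))
})

test_that("angle-averaged GLCM/GLRLM features are invariant to in-plane rotation", {
  set.seed(7)
  vals <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  mask <- array(TRUE, c(6, 6, 3))
  rot <- function(a) {
    out <- array(0, dim(a)[c(2, 1, 3)])
    for (k in seq_len(dim(a)[3])) out[, , k] <- t(a[, , k])[dim(a)[2]:1, ]
    out
  }
  f1 <- texture_features(texture_matrices(discretize(vals, mask, 4)))
  f2 <- texture_features(texture_matrices(discretize(rot(vals), mask, 4)))
  pick <- grep("^(glcm|glrlm)_", names(f1), value = TRUE)
  expect_equal(f1[pick], f2[pick], tolerance = 1e-12)
})

test_that("every matrix feature agrees with the brute-force oracle", {
  for (s in c(5, 23, 77)) {
    r <- random_dimg(s)
    dimg <- as_dimg(r$lev, r$mask, r$ng)
    impl <- texture_features(texture_matrices(dimg))
    orac <- o_texture_features(r$lev, r$ng, sum(r$mask))[names(impl)]
    expect_equal(impl, orac, tolerance = 1e-12)
  }
})

test_that("degenerate single-level regions flag correlation-type features", {
  dc <- discretize(array(4, c(3, 3, 2)), array(TRUE, c(3, 3, 2)), 8)
  tf <- texture_features(texture_matrices(dc))
  expect_true(is.na(tf["glcm_Correlation"]))
  expect_false(any(is.nan(tf)))
})
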