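shape_small <- list(fov_mm = c(40, 40, 24), semi_axes_mm = c(8, 7, 5),
                    edema_scale = 1.4)

test_that("phantom generation is deterministic and piecewise constant without noise", {
  prof <- scanner_profile(c(1, 1), 2, bias_amplitude = 0.3, noise_sd = 0.02)
  v1 <- generate_tumor_volume(prof, shape_small, seed = 11)
  v2 <- generate_tumor_volume(prof, shape_small, seed = 11)
  expect_identical(v1, v2)

  clean <- generate_tumor_volume(scanner_profile(c(1, 1), 2, 0, 0),
                                 shape_small, seed = 11)
  expect_setequal(unique(as.vector(clean$t1$values)),
                  unname(clean$levels$T1Gd))
  expect_setequal(unique(as.vector(clean$t2$values)),
                  unname(clean$levels$T2))
  # bright rim, dark core on T1
  expect_gt(max(clean$t1$values[clean$t1_mask]),
            clean$levels$T1Gd[["background"]])
  expect_lt(min(clean$t1$values[clean$t1_mask]),
            clean$levels$T1Gd[["background"]])
})

test_that("mask geometry invariants hold and oversized tumors are rejected", {
  prof <- scanner_profile(c(1, 1), 2, 0.2, 0.02)
  v <- generate_tumor_volume(prof, shape_small, seed = 3)
  expect_true(all(dim(v$t1_mask) == dim(v$t1$values)))
  expect_true(all(v$t2_mask[v$t1_mask]))          # edema mask contains tumor
  expect_lte(sum(v$t1_mask), sum(v$t2_mask))
  expect_gt(sum(v$t1_mask), 0)
  expect_error(generate_tumor_volume(prof, list(fov_mm = c(30, 30, 10),
                                                semi_axes_mm = c(20, 20, 20)),
                                     seed = 1),
               "field of view")
})

test_that("bias field skews intensity ratios and correction shrinks the skew", {
  prof <- scanner_profile(c(1, 1), 2, bias_amplitude = 0.3, noise_sd = 0)
  v <- generate_tumor_volume(prof, shape_small, seed = 21)
  d1 <- dim(v$t1$values)[1]
  left <- v$t1_mask; left[(d1 %/% 2 + 1):d1, , ] <- FALSE
  right <- v$t1_mask & !left
  ratio <- function(img) mean(img$values[left]) / mean(img$values[right])
  raw_dev <- abs(ratio(v$t1) - 1)
  corr_dev <- abs(ratio(correct_bias_field(v$t1)) - 1)
  expect_gt(raw_dev, 0.005)
  expect_lt(corr_dev, raw_dev)
})

test_that("survival generator matches its log-linear hazard", {
  # censoring limit: censor_rate -> 0 makes nearly everything an event
  gt_lo <- ground_truth(beta_surv = c(x = 0), censor_rate = 1e-9, seed = 5)
  sv <- simulate_survival(data.frame(x = rnorm(400)), gt_lo)
  expect_gt(mean(sv$event), 0.99)

  # null model: log-rank p on a feature split is not systematically small
  gt0 <- ground_truth(beta_surv = c(x = 0), censor_rate = 0.02, seed = 5)
  ps <- vapply(1:20, function(s) {
    x <- rep(c(0, 1), each = 100)
    sv <- simulate_survival(data.frame(x = x), gt0, seed = s)
    sd <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ x)
    stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.3)         # ~nominal false-positive rate

  # empirical hazard ratio converges to exp(beta)
  gt1 <- ground_truth(beta_surv = c(x = 1), censor_rate = 1e-9, seed = 7)
  x <- rep(c(0, 1), each = 2500)
  sv <- simulate_survival(data.frame(x = x), gt1, seed = 77)
  hr_emp <- mean(sv$time[x == 0]) / mean(sv$time[x == 1])
  expect_lt(abs(hr_emp - exp(1)) / exp(1), 0.10)

  # Cox fit recovers beta within 3 SE at n = 2000
  set.seed(42)
  xg <- rnorm(2000)
  svg <- simulate_survival(data.frame(x = xg),
                           ground_truth(beta_surv = c(x = 1),
                                        censor_rate = 0.01, seed = 9))
  m <- fit_cox(data.frame(x = xg), svg)
  expect_lt(abs(unname(coef(m)["x"]) - 1), 3 * unname(m$se["x"]))

  expect_error(ground_truth(baseline_hazard_rate = 0), "positive")
  expect_error(simulate_survival(data.frame(z = 1:3),
                                 ground_truth(beta_surv = c(x = 1))),
               "missing")
})

test_that("cohort generation honours sizes, marker missingness and scanner mixtures", {
  co <- generate_cohorts(n_train = 142, n_val = 46, images = FALSE,
                         gt = ground_truth(seed = 4),
                         missing_marker_frac = 0)
  expect_equal(nrow(co$train$clinical), 142)
  expect_equal(nrow(co$val$clinical), 46)
  expect_false(anyNA(co$train$markers[-1]))
  expect_false(anyNA(co$val$markers[-1]))
  expect_equal(nrow(co$train$survival), 142)

  co2 <- generate_cohorts(n_train = 60, n_val = 60, images = FALSE,
                          gt = ground_truth(seed = 4),
                          missing_marker_frac = 0.3)
  expect_gt(sum(is.na(co2$train$markers$MGMT)), 0)

  # scanner mixtures differ between cohorts (two-sample distribution test)
  kt <- suppressWarnings(stats::ks.test(co2$train$spacings$dx,
                                        co2$val$spacings$dx))
  expect_lt(kt$p.value, 0.05)

  # identical ground truth regenerates identical tables
  co3 <- generate_cohorts(n_train = 60, n_val = 60, images = FALSE,
                          gt = ground_truth(seed = 4),
                          missing_marker_frac = 0.3)
  expect_identical(co2$train, co3$train)
})

test_that("cohort files round-trip through the on-disk formats", {
  td <- withr::local_tempdir()
  co <- generate_cohorts(n_train = 2, n_val = 2, images = TRUE,
                         gt = ground_truth(seed = 6),
                         image_params = list(fov_mm = c(40, 40, 24),
                                             semi_axes_mm = c(8, 7, 5),
                                             edema_scale = 1.4),
                         out_dir = td)
  expect_true(file.exists(file.path(td, "train", "clinical.csv")))
  expect_true(file.exists(file.path(td, "ground_truth.json")))
  gt_back <- jsonlite::read_json(file.path(td, "ground_truth.json"),
                                 simplifyVector = TRUE)
  expect_equal(gt_back$seed, 6)
  img <- read_nifti_volume(file.path(td, "train", "train_001_t1.nii.gz"))
  expect_equal(dim(img), dim(co$train$patients[[1]]$volumes$t1$values))
  expect_equal(img$spacing, co$train$patients[[1]]$volumes$t1$spacing,
               tolerance = 1e-6)
})
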