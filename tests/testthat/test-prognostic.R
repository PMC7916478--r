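sim_cohort <- function(n, beta, seed, p_noise = 0, censor = 0.02) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * (length(beta) + p_noise)), n))
  names(X) <- c(names(beta), if (p_noise) sprintf("noise%02d", seq_len(p_noise)))
  sv <- simulate_survival(X, ground_truth(beta_surv = beta,
                                          censor_rate = censor, seed = seed),
                          seed = seed + 1)
  list(X = X, surv = sv)
}

test_that("univariate screening keeps informative features and obeys alpha", {
  d <- sim_cohort(500, c(sig = 1), 21, p_noise = 8)
  d$X$flat <- 0
  sel <- univariate_cox_screen(d$X, d$surv)
  expect_true("sig" %in% sel)
  expect_false("flat" %in% sel)

  all_sel <- univariate_cox_screen(d$X[, 1:5], d$surv, alpha = 1)
  expect_setequal(as.character(all_sel), names(d$X)[1:5])
  expect_error(univariate_cox_screen(d$X,
                                     data.frame(time = 1:5, event = 0)),
               "event")
})

test_that("correlation elimination is strict, deterministic, and keeps duplicates once", {
  set.seed(22)
  X <- data.frame(a = rnorm(100))
  X$b <- X$a                               # exact duplicate
  X$c <- rnorm(100)
  keep <- eliminate_correlated(X)
  expect_setequal(keep, c("a", "c"))

  # a pair at exactly the threshold is retained (strict inequality)
  X2 <- data.frame(u = stats::rnorm(50), v = stats::rnorm(50))
  rs <- stats::cor(X2$u, X2$v, method = "spearman")
  keep2 <- eliminate_correlated(X2, threshold = abs(rs))
  expect_setequal(keep2, c("u", "v"))

  # independent features all survive
  X3 <- as.data.frame(matrix(rnorm(300), 100, 3))
  expect_length(eliminate_correlated(X3), 3)

  # priority rule keeps the smaller-p member
  X4 <- data.frame(good = rnorm(80))
  X4$bad <- X4$good + rnorm(80, 0, 0.01)
  keep4 <- eliminate_correlated(X4, priority = c(good = 0.01, bad = 0.5))
  expect_equal(keep4, "good")
})

test_that("Cox fitting recovers parameters and handles degenerate inputs", {
  d <- sim_cohort(2000, c(x = 1), 23)
  m <- fit_cox(d$X, d$surv)
  expect_lt(abs(unname(coef(m)["x"]) - 1), 3 * unname(m$se["x"]))
  expect_equal(unname(m$hr["x"]), exp(unname(coef(m)["x"])))

  # all-zero feature gets an exact zero coefficient
  d$X$null <- 0
  m2 <- fit_cox(d$X, d$surv)
  expect_identical(unname(coef(m2)["null"]), 0)

  # direction: the shorter-surviving group gets a positive log-hazard
  grp <- rep(c(0, 1), each = 50)
  sv <- data.frame(time = c(rexp(50, 0.1), rexp(50, 1)), event = 1)
  m3 <- fit_cox(data.frame(g = grp), sv)
  expect_gt(unname(coef(m3)["g"]), 0)

  expect_error(fit_cox(as.data.frame(matrix(rnorm(50), 5)),
                       data.frame(time = 1:5, event = c(1, 0, 0, 0, 0))),
               "fewer events")
})

test_that("backward elimination keeps signal, removes noise at the nominal rate", {
  d <- sim_cohort(600, c(s1 = 0.8, s2 = 0.8), 24, p_noise = 6)
  m <- backward_eliminate(d$X, d$surv, alpha = 0.2)
  expect_true(all(c("s1", "s2") %in% names(m$p)))
  expect_true(all(m$p <= 0.2))

  full <- fit_cox(d$X[, c("s1", "s2")], d$surv)
  unchanged <- backward_eliminate(d$X[, c("s1", "s2")], d$surv, alpha = 0.2)
  expect_equal(coef(unchanged), coef(full))

  # null features are retained at roughly the removal alpha
  retained <- vapply(1:40, function(s) {
    dn <- sim_cohort(150, c(z = 0), s + 100, p_noise = 0)
    m0 <- backward_eliminate(dn$X, dn$surv, alpha = 0.2)
    length(m0$p) == 1
  }, logical(1))
  expect_gt(mean(retained), 0.05)
  expect_lt(mean(retained), 0.45)
})

test_that("the prognostic index is a centred linear score", {
  m <- cox_model(c(subependymal_extension = log(1.75),
                   t1_flair_increased = log(0.59)))
  pt <- data.frame(subependymal_extension = 1, t1_flair_increased = 1)
  expect_equal(compute_pi(m, pt), log(1.75) + log(0.59), tolerance = 1e-4,
               ignore_attr = TRUE)

  # centering cancels in differences
  m2 <- m; m2$pi_center <- 3
  two <- data.frame(subependymal_extension = c(1, 0),
                    t1_flair_increased = c(0, 1))
  expect_equal(diff(compute_pi(m, two)), diff(compute_pi(m2, two)),
               ignore_attr = TRUE)

  expect_equal(unique(compute_pi(empty_model <- gliomix:::empty_cox_model(),
                                 data.frame(a = 1:3))), 0)

  # missing feature values exclude the patient with a log entry
  pt2 <- data.frame(subependymal_extension = c(1, NA),
                    t1_flair_increased = c(1, 1))
  pi2 <- compute_pi(m, pt2)
  expect_true(is.na(pi2[2]))
  expect_equal(attr(pi2, "excluded"), 2L)
})

test_that("PI stacking requires independent components and finds their weights", {
  d <- sim_cohort(2000, c(x = 1), 26)
  m <- fit_cox(d$X, d$surv)
  pi1 <- compute_pi(m, d$X)
  noise <- rnorm(2000)
  st <- stack_pi(data.frame(real = pi1, noise = noise), d$surv)
  expect_lt(abs(unname(coef(st)["noise"])), 0.1)
  expect_gt(unname(coef(st)["real"]), 0.8)
  expect_equal(length(st$hr), 2L)

  expect_error(stack_pi(data.frame(a = pi1, b = pi1), d$surv), "collinear")
  expect_error(stack_pi(data.frame(a = pi1), d$surv), "at least two")

  # three components are accepted with three hazard ratios
  st3 <- stack_pi(data.frame(a = pi1, b = noise, c = rnorm(2000)), d$surv)
  expect_length(st3$hr, 3L)
})

test_that("the clinical model enters all covariates and checks its schema", {
  set.seed(27)
  n <- 400
  cl <- data.frame(
    sex = sample(c("male", "female"), n, TRUE),
    surgery = sample(c("biopsy", "resection"), n, TRUE),
    age = runif(n, 40, 80),
    adjuvant = sample(c("STUPP", "non-STUPP"), n, TRUE),
    mgmt_methylated = rbinom(n, 1, 0.3))
  lat <- data.frame(adjuvant_non_stupp = as.numeric(cl$adjuvant != "STUPP"))
  sv <- simulate_survival(lat, ground_truth(
    beta_surv = c(adjuvant_non_stupp = 1.6), censor_rate = 0.02, seed = 1))
  m <- clinical_model(cl, sv)
  expect_setequal(names(coef(m)),
                  c("sex_male", "surgery_resection", "age_over_70",
                    "adjuvant_non_stupp", "mgmt_methylated"))
  expect_lt(abs(unname(coef(m)["adjuvant_non_stupp"]) - 1.6),
            3 * unname(m$se["adjuvant_non_stupp"]))

  expect_error(clinical_model(cl[, setdiff(names(cl), "mgmt_methylated")], sv),
               "mgmt")
})

test_that("concordance, calibration and misspecification diagnostics behave", {
  expect_equal(harrell_c(c(3, 2, 1), data.frame(time = 1:3, event = 1),
                         n_boot = 20)$c_index, 1)
  expect_equal(harrell_c(rep(1, 4), data.frame(time = 1:4, event = 1),
                         n_boot = 20)$c_index, 0.5)

  d <- sim_cohort(800, c(x = 0.8), 28)
  m <- fit_cox(d$X, d$surv)
  pi_tr <- compute_pi(m, d$X)

  cs <- calibration_slope(pi_tr, d$surv)
  expect_equal(cs$slope, 1, tolerance = 1e-6)

  mt <- misspecification_test(d$X, m, d$surv)
  expect_lt(abs(mt$statistic), 1e-6)
  expect_equal(mt$p, 1, tolerance = 1e-6)

  # independent validation from the same generator: slope near 1
  dv <- sim_cohort(800, c(x = 0.8), 29)
  cs2 <- calibration_slope(compute_pi(m, dv$X), dv$surv)
  expect_lt(abs(cs2$slope - 1), 4 * cs2$se)

  # a noise-trained model transfers with slope near 0
  slopes <- vapply(1:10, function(s) {
    dn <- sim_cohort(150, c(z = 0), 300 + s, p_noise = 3)
    mn <- fit_cox(dn$X[, -1], dn$surv)
    dvn <- sim_cohort(300, c(z = 0), 400 + s, p_noise = 3)
    calibration_slope(compute_pi(mn, dvn$X[, -1]), dvn$surv)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.35)

  expect_error(misspecification_test(d$X, gliomix:::empty_cox_model(),
                                     d$surv), "undefined")
})

test_that("risk-group splitting freezes the training threshold", {
  d <- sim_cohort(600, c(x = 1), 31)
  m <- fit_cox(d$X, d$surv)
  pi_tr <- compute_pi(m, d$X)
  dv <- sim_cohort(300, c(x = 1), 32)
  pi_v <- compute_pi(m, dv$X)

  ks <- km_split(pi_tr, d$surv, pi_v, dv$surv)
  expect_equal(ks$threshold,
               stats::quantile(pi_tr, 0.75, type = 7, names = FALSE))
  expect_lt(ks$train$logrank_p, 0.001)
  expect_lt(ks$val$logrank_p, 0.001)
  expect_named(ks$val$predicted, c("time", "low", "high"))
  # predicted curves are survival curves
  expect_true(all(diff(ks$val$predicted$low) <= 1e-12))
  expect_true(all(ks$val$predicted$high <= ks$val$predicted$low + 1e-8))

  # a null PI produces no separation
  ks0 <- km_split(rnorm(600), d$surv)
  expect_gt(ks0$train$logrank_p, 0.001)

  # threshold is unaffected by the validation distribution
  ks2 <- km_split(pi_tr, d$surv, pi_v + 100, dv$surv)
  expect_equal(ks2$threshold, ks$threshold)
})

test_that("volume and cross-block correlation checks", {
  set.seed(33)
  vol <- runif(60, 1e3, 3e4)
  X <- data.frame(self = vol, perm = sample(vol), other = rnorm(60))
  vc <- volume_correlation_check(X, vol)
  expect_equal(vc$rs[vc$feature == "self"], 1)
  expect_lt(abs(vc$rs[vc$feature == "perm"]), 0.35)

  bin <- as.numeric(X$other > 0)
  cb <- cross_block_correlation(data.frame(b = bin, z = rnorm(60)),
                                data.frame(cont = X$other, flat = 1))
  expect_equal(attr(cb, "skipped"), "flat")
  r_bc <- cb$r[cb$feature_a == "b" & cb$feature_b == "cont"]
  expect_gt(r_bc, 0.5)            # thresholded copy: near-maximal pb corr
  expect_equal(cb$method[cb$feature_a == "b" & cb$feature_b == "cont"],
               "point-biserial")
  # symmetry in argument order
  cb2 <- cross_block_correlation(data.frame(cont = X$other),
                                 data.frame(b = bin))
  expect_equal(r_bc, cb2$r[1])
})
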