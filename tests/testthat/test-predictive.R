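make_marker_data <- function(n = 120, p = 20, k = 3, beta = 1.2, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- sprintf("f%02d", seq_len(p))
  eta <- as.matrix(X[, seq_len(k), drop = FALSE]) %*% rep(beta, k)
  y <- rbinom(n, 1, stats::plogis(eta))
  list(X = X, y = y)
}

test_that("the rank AUC handles ties and perfect orderings", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_score(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_equal(auc_score(c(0, 1), c(0.3, 0.3)), 0.5)
  expect_error(auc_score(c(1, 1), c(0.2, 0.3)), "both classes")
  # cross-check against the ROC ecosystem implementation
  set.seed(5)
  y <- rbinom(60, 1, 0.5); pr <- runif(60)
  skip_if_not_installed("pROC")
  expect_equal(auc_score(y, pr),
               as.numeric(pROC::auc(pROC::roc(y, pr, quiet = TRUE))))
})

test_that("AUC-guided correlation elimination keeps the informative member", {
  d <- make_marker_data(seed = 6)
  X <- d$X
  X$dup <- X$f01                          # duplicate of a predictive feature
  keep <- eliminate_correlated_by_auc(X, d$y)
  expect_true(xor("f01" %in% keep, "dup" %in% keep))

  # noisy copy loses to the signal it copies
  wins <- vapply(1:20, function(s) {
    dd <- make_marker_data(n = 300, p = 3, k = 1, beta = 1.5, seed = 50 + s)
    dd$X$copy <- dd$X$f01 + rnorm(300, 0, 0.45)
    "f01" %in% eliminate_correlated_by_auc(dd$X, dd$y, 0.85)
  }, logical(1))
  expect_gte(mean(wins), 0.9)

  keep_all <- eliminate_correlated_by_auc(d$X, d$y, threshold = 1.0)
  expect_length(keep_all, ncol(d$X))
})

test_that("stratified splits preserve proportions and vary by seed", {
  y <- rep(c(0, 1), each = 50)
  sp <- stratified_split(y, 0.7, seed = 2)
  expect_length(sp$train, 70)
  expect_equal(sum(y[sp$train]), 35)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_identical(sp, stratified_split(y, 0.7, seed = 2))

  splits <- lapply(1:10, function(s) stratified_split(y, 0.7, seed = s)$train)
  expect_equal(length(unique(splits)), 10L)

  expect_error(stratified_split(c(0, 1, 1, 1), 0.7, 1), "at least 2")
})

test_that("cumulative importance ranks planted features first", {
  d <- make_marker_data(n = 150, p = 10, k = 1, beta = 3, seed = 7)
  d$X$f01 <- as.numeric(d$y)              # feature equal to the label
  r <- rf_importance_rank(d$X, d$y, n_iter = 30, seed = 3, top_k = 5)
  expect_equal(r$ranking$feature[1], "f01")
  expect_length(r$top, 5)
  # fewer candidates than top_k keeps everything
  r2 <- rf_importance_rank(d$X[, 1:3], d$y, n_iter = 5, seed = 3, top_k = 20)
  expect_length(r2$top, 3)
  # longer accumulation stabilises the ranking
  ra <- rf_importance_rank(d$X, d$y, n_iter = 1, seed = 11, top_k = 10)
  rb <- rf_importance_rank(d$X, d$y, n_iter = 40, seed = 12, top_k = 10)
  rc <- rf_importance_rank(d$X, d$y, n_iter = 40, seed = 13, top_k = 10)
  tau_long <- stats::cor(match(rb$ranking$feature, rc$ranking$feature),
                         seq_len(10), method = "kendall")
  expect_gt(tau_long, 0.5)
})

test_that("randomized search finds separable structure and is reproducible", {
  set.seed(8)
  n <- 80
  X <- data.frame(a = c(rnorm(n / 2, -3), rnorm(n / 2, 3)), b = rnorm(n))
  y <- rep(c(0, 1), each = n / 2)
  sr <- model_search(X[seq(1, n, 2), ], y[seq(1, n, 2)],
                     X[seq(2, n, 2), ], y[seq(2, n, 2)],
                     n_iter = 30, seed = 4)
  expect_equal(sr[[1]]$auc, 1)
  sr2 <- model_search(X[seq(1, n, 2), ], y[seq(1, n, 2)],
                      X[seq(2, n, 2), ], y[seq(2, n, 2)],
                      n_iter = 30, seed = 4)
  expect_identical(lapply(sr, `[`, c("family", "params", "auc")),
                   lapply(sr2, `[`, c("family", "params", "auc")))
  expect_setequal(unique(vapply(sr, `[[`, "", "family")),
                  c("xgboost", "random_forest", "logistic"))
})

test_that("repeated splits temper the lucky-split optimism", {
  d <- make_marker_data(n = 120, p = 6, k = 2, beta = 1.5, seed = 9)
  sp <- stratified_split(d$y, 0.7, 5)
  sr <- model_search(d$X[sp$train, ], d$y[sp$train], d$X[sp$test, ],
                     d$y[sp$test], n_iter = 20, seed = 5)
  top <- utils::head(sr, 3)
  ev <- repeated_split_eval(top, d$X, d$y, n_repeats = 5, seed = 6)
  expect_equal(dim(ev$auc_matrix), c(3L, 5L))
  expect_true(all(ev$summary$mean_auc > 0.5))
  expect_true(ev$best$family %in% c("xgboost", "random_forest", "logistic"))

  # single repeat reduces to a single-split evaluation
  ev1 <- repeated_split_eval(top, d$X, d$y, n_repeats = 1, seed = 6)
  expect_equal(ncol(ev1$auc_matrix), 1L)

  # null labels: search winner's test AUC exceeds its repeated-split mean
  dn <- make_marker_data(n = 80, p = 8, k = 0, seed = 10)
  spn <- stratified_split(dn$y, 0.7, 7)
  srn <- model_search(dn$X[spn$train, ], dn$y[spn$train], dn$X[spn$test, ],
                      dn$y[spn$test], n_iter = 25, seed = 7)
  evn <- repeated_split_eval(utils::head(srn, 3), dn$X, dn$y,
                             n_repeats = 6, seed = 8)
  expect_gt(srn[[1]]$auc, max(evn$summary$mean_auc) - 0.05)
})

test_that("probability ensembling is an elementwise mean with guardrails", {
  expect_equal(ensemble_average(c(0.2, 0.8), c(0.4, 0.6)), c(0.3, 0.7))
  p <- c(0.1, 0.5, 0.9)
  expect_equal(ensemble_average(p, p), p)
  expect_equal(ensemble_average(p, rev(p)), ensemble_average(rev(p), p))
  expect_error(ensemble_average(c(0.1, 0.2), 0.1), "length")
  expect_error(ensemble_average(c(0.1, 2), c(0.1, 0.2)), "0, 1")

  # two independent noisy views of one signal: ensemble at least as good as
  # the weaker view, on average better than both
  res <- vapply(1:15, function(s) {
    set.seed(700 + s)
    sig <- rnorm(300)
    y <- rbinom(300, 1, stats::plogis(1.5 * sig))
    pa <- stats::plogis(sig + rnorm(300, 0, 1))
    pb <- stats::plogis(sig + rnorm(300, 0, 1))
    c(a = auc_score(y, pa), b = auc_score(y, pb),
      e = auc_score(y, ensemble_average(pa, pb)))
  }, numeric(3))
  expect_gt(mean(res["e", ]), mean(res["a", ]))
  expect_gt(mean(res["e", ]), mean(res["b", ]))
})

test_that("bootstrap AUC intervals behave at the extremes", {
  y <- rep(c(0, 1), each = 20)
  perfect <- bootstrap_auc_ci(y, c(rep(0.1, 20), rep(0.9, 20)), n_boot = 50,
                              seed = 3)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$ci_lower, 1)
  expect_equal(perfect$ci_upper, 1)

  const <- bootstrap_auc_ci(y, rep(0.4, 40), n_boot = 50, seed = 3)
  expect_equal(const$auc, 0.5)
  expect_equal(const$ci_lower, 0.5)
  expect_equal(const$ci_upper, 0.5)

  expect_error(bootstrap_auc_ci(rep(1, 10), runif(10), 10), "both classes")
})

test_that("heterogeneity histograms pair Mann-Whitney tests with Bonferroni", {
  set.seed(11)
  base <- rnorm(100)
  # `same` has literally identical class distributions
  X <- data.frame(same = c(base, base), shift = rnorm(200))
  y <- rep(c(0, 1), each = 100)
  X$shift[y == 1] <- X$shift[y == 1] + 1
  h <- heterogeneity_histograms(X, y)
  expect_lt(h$p_adj[h$feature == "shift"], 0.05)
  expect_gt(h$p_adj[h$feature == "same"], 0.9)
  expect_true(all(h$p_adj >= h$p))
  expect_true(all(h$p_adj <= 1))

  X$tied <- 1
  h2 <- heterogeneity_histograms(X, y)
  expect_equal(h2$p[h2$feature == "tied"], 1)
  expect_length(attr(h2, "histograms"), 3L)
})
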