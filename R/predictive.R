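#' Area under the ROC curve (tie-corrected rank formulation)
#'
#' Mann-Whitney AUC: tied scores contribute 1/2. A constant score gives 0.5.
#'
#' @param y binary 0/1 labels.
#' @param probs numeric scores.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(y, probs) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(probs)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Correlation elimination keeping the higher univariate AUC
#'
#' For every feature pair whose absolute Spearman correlation strictly
#' exceeds the threshold, the member with the lower univariate ROC AUC
#' (folded: `max(auc, 1 - auc)`) is removed; AUC ties are broken by keeping
#' the lexicographically smaller id. Greedy on the most correlated remaining
#' pair; deterministic.
#'
#' @param X feature data frame. @param y binary labels.
#' @param threshold Spearman threshold (strict).
#' @return Character vector of surviving feature ids with attribute
#'   `"auc"` (per-feature folded univariate AUC).
#' @export
eliminate_correlated_by_auc <- function(X, y, threshold = 0.85) {
  X <- as.data.frame(X)
  aucs <- vapply(X, function(x) {
    if (stats::sd(x) == 0) return(0.5)
    a <- auc_score(y, x)
    max(a, 1 - a)
  }, numeric(1))
  keep <- names(X)
  if (length(keep) >= 2) {
    cm <- suppressWarnings(stats::cor(X, method = "spearman"))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    repeat {
      sub <- abs(cm[keep, keep, drop = FALSE])
      mx <- max(sub)
      if (mx <= threshold) break
      w <- which(sub == mx, arr.ind = TRUE)[1, ]
      a <- keep[w[1]]; b <- keep[w[2]]
      drop_f <- if (aucs[a] != aucs[b]) {
        if (aucs[a] < aucs[b]) a else b
      } else max(a, b)               # keep the lexicographically smaller id
      keep <- setdiff(keep, drop_f)
      if (length(keep) < 2) break
    }
  }
  structure(keep, auc = aucs)
}

#' Label-stratified random train/test split
#'
#' Splits indices into train/test preserving the class proportions within
#' one patient. Disjoint and exhaustive; reproducible under the seed.
#'
#' @param y binary labels. @param ratio training fraction. @param seed seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, ratio = 0.7, seed = 1L) {
  y <- as.integer(y)
  if (any(table(y) < 2)) stop("each class needs at least 2 members", call. = FALSE)
  with_seed(seed, {
    tr <- integer(0)
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      n_tr <- round(ratio * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      tr <- c(tr, sample(idx, n_tr))
    }
    tr <- sort(tr)
    list(train = tr, test = setdiff(seq_along(y), tr))
  })
}

#' Hyperparameter sampling ranges for the three learner families
#'
#' Tree count and depth ranges follow the published search ranges
#' (estimators 20-300, depth 2-6); the remaining ranges (learning rate and
#' subsampling for boosted trees, ridge penalty for logistic regression,
#' feature-subsampling fraction for forests) are package defaults.
#'
#' @return Named list of per-family ranges.
#' @export
hyperparameter_ranges <- function() {
  list(
    random_forest = list(num_trees = c(20, 300), max_depth = c(2, 6),
                         mtry_frac = c(0.2, 0.8)),
    xgboost = list(nrounds = c(20, 300), max_depth = c(2, 6),
                   log_eta = log(c(0.01, 0.3)), subsample = c(0.6, 1)),
    logistic = list(log_lambda = c(log(1e-3), log(10))))
}

sample_hyperparams <- function(family, ranges) {
  r <- ranges[[family]]
  ri <- function(b) sample(seq(b[1], b[2]), 1L)
  ru <- function(b) stats::runif(1, b[1], b[2])
  switch(family,
    random_forest = list(num_trees = ri(r$num_trees),
                         max_depth = ri(r$max_depth),
                         mtry_frac = ru(r$mtry_frac)),
    xgboost = list(nrounds = ri(r$nrounds), max_depth = ri(r$max_depth),
                   eta = exp(ru(r$log_eta)), subsample = ru(r$subsample)),
    logistic = list(lambda = exp(ru(r$log_lambda))))
}

train_candidate <- function(family, params, X, y, seed = 1L) {
  X <- as.matrix(X)
  switch(family,
    random_forest = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$num_trees, max.depth = params$max_depth,
      mtry = max(1L, floor(params$mtry_frac * ncol(X))),
      seed = seed, num.threads = 1),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$max_depth,
                    eta = params$eta, subsample = params$subsample,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = params$nrounds,
      verbose = 0),
    logistic = {
      Xg <- if (ncol(X) < 2) cbind(X, .pad = 0) else X
      glmnet::glmnet(Xg, factor(y, levels = c(0, 1)), family = "binomial",
                     alpha = 0, lambda = params$lambda)
    })
}

predict_candidate <- function(model, family, X) {
  X <- as.matrix(X)
  switch(family,
    random_forest = stats::predict(model, data = X,
                                   num.threads = 1)$predictions[, "1"],
    xgboost = stats::predict(model, xgboost::xgb.DMatrix(X)),
    logistic = {
      Xg <- if (ncol(X) < 2) cbind(X, .pad = 0) else X
      drop(stats::predict(model, Xg, type = "response"))
    })
}

#' Cumulative random-forest feature importance ranking
#'
#' Fits `n_iter` random forests with hyperparameters sampled uniformly from
#' the declared ranges, accumulates Gini impurity importances into a
#' cumulative histogram, and selects the `top_k` features by cumulative
#' importance. With fewer than `top_k` candidates all are kept. Constant
#' columns accumulate zero importance and rank last.
#'
#' @param X features. @param y binary labels.
#' @param n_iter forest fits.
#' @param ranges from [hyperparameter_ranges()].
#' @param seed master seed (per-fit seeds derived from it).
#' @param top_k features to keep.
#' @return List: `top` (character), `ranking` (data frame, descending
#'   cumulative importance).
#' @export
rf_importance_rank <- function(X, y, n_iter = 1000L,
                               ranges = hyperparameter_ranges(), seed = 1L,
                               top_k = 20L) {
  X <- as.data.frame(X)
  cum <- stats::setNames(rep(0, ncol(X)), names(X))
  for (i in seq_len(n_iter)) {
    si <- derive_seed(seed, i)
    params <- with_seed(si, sample_hyperparams("random_forest", ranges))
    fit <- ranger::ranger(x = as.matrix(X), y = factor(y, levels = c(0, 1)),
                          num.trees = params$num_trees,
                          max.depth = params$max_depth,
                          mtry = max(1L, floor(params$mtry_frac * ncol(X))),
                          importance = "impurity", seed = si, num.threads = 1)
    imp <- fit$variable.importance
    cum[names(imp)] <- cum[names(imp)] + imp
  }
  ord <- order(-cum, names(cum))
  ranking <- data.frame(feature = names(cum)[ord],
                        cumulative_importance = unname(cum[ord]))
  list(top = ranking$feature[seq_len(min(top_k, nrow(ranking)))],
       ranking = ranking)
}

#' Randomized hyperparameter model search
#'
#' Draws `n_iter` candidates -- a learner family sampled uniformly from
#' `families`, hyperparameters sampled uniformly from their ranges -- trains
#' each on the training split and scores it by AUC on the test split.
#' Candidates that fail to train are recorded with an undefined score and
#' excluded from the ranking. Fully reproducible under the master seed.
#'
#' @param X_train,y_train,X_test,y_test the split data.
#' @param families learner families to sample from.
#' @param n_iter number of candidates.
#' @param ranges from [hyperparameter_ranges()].
#' @param seed master seed.
#' @return Object of class `gx_search_result`: list of candidates (family,
#'   params, auc), ranked by descending test AUC (ties by draw order).
#' @export
model_search <- function(X_train, y_train, X_test, y_test,
                         families = c("xgboost", "random_forest", "logistic"),
                         n_iter = 1000L, ranges = hyperparameter_ranges(),
                         seed = 1L) {
  cands <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    si <- derive_seed(seed, 7000L + i)
    family <- with_seed(si, sample(families, 1L))
    params <- with_seed(derive_seed(si, 1L),
                        sample_hyperparams(family, ranges))
    auc <- tryCatch({
      fit <- train_candidate(family, params, X_train, y_train, seed = si)
      auc_score(y_test, predict_candidate(fit, family, X_test))
    }, error = function(e) NA_real_)
    cands[[i]] <- list(iter = i, family = family, params = params, auc = auc)
  }
  aucs <- vapply(cands, function(c) ifelse(is.na(c$auc), -Inf, c$auc),
                 numeric(1))
  structure(cands[order(-aucs, vapply(cands, `[[`, 0L, "iter"))],
            class = "gx_search_result")
}

#' @export
print.gx_search_result <- function(x, n = 5L, ...) {
  cat(sprintf("<gx_search_result: %d candidates>\n", length(x)))
  for (c in utils::head(x, n))
    cat(sprintf("  %-14s AUC=%.3f  %s\n", c$family,
                ifelse(is.na(c$auc), NaN, c$auc),
                paste(names(c$params), signif(unlist(c$params), 3),
                      sep = "=", collapse = " ")))
  invisible(x)
}

#' Repeated-split evaluation of the top candidates
#'
#' Guards against a "lucky split": the stratified split is redrawn
#' `n_repeats` times with fresh derived seeds, every candidate is retrained
#' and rescored per split, and the final model is the candidate with the
#' best mean AUC.
#'
#' @param top_models list of candidates (as from [model_search()], usually
#'   the top 5).
#' @param X,y the full modelling cohort.
#' @param n_repeats number of fresh splits.
#' @param ratio training fraction.
#' @param seed master seed.
#' @return List: `summary` (per-candidate mean/sd of AUC), `auc_matrix`
#'   (candidate x split), `best` (the winning candidate).
#' @export
repeated_split_eval <- function(top_models, X, y, n_repeats = 10L,
                                ratio = 0.7, seed = 1L) {
  X <- as.data.frame(X)
  aucm <- matrix(NA_real_, length(top_models), n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- stratified_split(y, ratio, seed = derive_seed(seed, 900L + r))
    for (m in seq_along(top_models)) {
      cand <- top_models[[m]]
      aucm[m, r] <- tryCatch({
        fit <- train_candidate(cand$family, cand$params,
                               X[sp$train, , drop = FALSE], y[sp$train],
                               seed = derive_seed(seed, 990L + r * 13L + m))
        auc_score(y[sp$test],
                  predict_candidate(fit, cand$family, X[sp$test, , drop = FALSE]))
      }, error = function(e) NA_real_)
    }
  }
  means <- rowMeans(aucm, na.rm = TRUE)
  summary <- data.frame(
    candidate = seq_along(top_models),
    family = vapply(top_models, `[[`, "", "family"),
    mean_auc = means,
    sd_auc = apply(aucm, 1, stats::sd, na.rm = TRUE))
  best <- top_models[[which.max(means)]]
  list(summary = summary, auc_matrix = aucm, best = best)
}

#' Average two predicted-probability vectors
#'
#' Elementwise arithmetic mean over the same patients; symmetric, idempotent
#' on identical inputs.
#'
#' @param probs_a,probs_b probabilities in [0, 1], equal length.
#' @return Averaged probabilities.
#' @export
ensemble_average <- function(probs_a, probs_b) {
  if (length(probs_a) != length(probs_b))
    stop("probability vectors differ in length", call. = FALSE)
  if (any(probs_a < 0 | probs_a > 1 | probs_b < 0 | probs_b > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  (probs_a + probs_b) / 2
}

#' Bootstrap confidence interval for the ROC AUC
#'
#' Patient-level resampling with replacement, percentile interval. Resamples
#' that lack one of the classes are redrawn (the count of redraws is
#' reported).
#'
#' @param y binary labels. @param probs scores.
#' @param n_boot bootstrap iterations.
#' @param conf confidence level.
#' @param seed seed.
#' @return List: `auc`, `ci_lower`, `ci_upper`, `n_boot`, `redraws`.
#' @export
bootstrap_auc_ci <- function(y, probs, n_boot = 100L, conf = 0.95, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  n <- length(y)
  redraws <- 0L
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    for (try in seq_len(1000L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2)
        return(auc_score(y[idx], probs[idx]))
      redraws <<- redraws + 1L
    }
    stop("could not draw a bootstrap resample containing both classes",
         call. = FALSE)
  }, numeric(1)))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), type = 7)
  list(auc = auc_score(y, probs), ci_lower = unname(qs[1]),
       ci_upper = unname(qs[2]), n_boot = n_boot, redraws = redraws)
}

#' Univariate outcome-heterogeneity assessment of selected features
#'
#' Per feature: class-conditional histograms plus the Mann-Whitney (Wilcoxon
#' rank-sum) test of a distributional difference between the two outcome
#' groups, Bonferroni-multiplied by the number of features and capped at 1.
#' An all-tied feature yields p = 1.
#'
#' @param X selected-feature data frame. @param y binary labels.
#' @return Data frame (feature, p, p_adj) with attribute `"histograms"`:
#'   per feature, shared breaks and per-class counts.
#' @export
heterogeneity_histograms <- function(X, y) {
  X <- as.data.frame(X)
  m <- ncol(X)
  hist_list <- list()
  rows <- lapply(names(X), function(nm) {
    x <- X[[nm]]
    p <- if (stats::sd(x) == 0) 1 else
      tryCatch(suppressWarnings(
        stats::wilcox.test(x[y == 1], x[y == 0], exact = FALSE)$p.value),
        error = function(e) 1)
    if (is.na(p)) p <- 1
    br <- if (stats::sd(x) == 0) c(x[1] - 0.5, x[1] + 0.5) else
      seq(min(x), max(x), length.out = 16L)
    hist_list[[nm]] <<- list(
      breaks = br,
      counts0 = graphics::hist(x[y == 0], breaks = br, plot = FALSE)$counts,
      counts1 = graphics::hist(x[y == 1], breaks = br, plot = FALSE)$counts)
    data.frame(feature = nm, p = p, p_adj = min(p * m, 1))
  })
  out <- do.call(rbind, rows)
  attr(out, "histograms") <- hist_list
  out
}
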