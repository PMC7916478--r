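#' Construct a Cox model object from known coefficients
#'
#' Useful for scoring patients with published or externally estimated
#' log-hazard coefficients (PI = sum(beta * x) - center).
#'
#' @param coefficients named numeric log-hazard coefficients.
#' @param pi_center centering constant.
#' @param tag cohort tag.
#' @return A `gx_cox_model`.
#' @export
cox_model <- function(coefficients, pi_center = 0, tag = "external") {
  stopifnot(!is.null(names(coefficients)), all(is.finite(coefficients)))
  m <- empty_cox_model(tag)
  m$coefficients <- coefficients
  m$features <- names(coefficients)
  m$pi_center <- pi_center
  m$hr <- exp(coefficients)
  m
}

# Radiomics block preparation: drop undefined / constant columns, Z-score
# with training-derived parameters transferred to validation.
prepare_radiomics_block <- function(train_features, val_features = NULL) {
  tf <- as.data.frame(train_features)
  keep <- vapply(tf, function(x) all(is.finite(x)) && stats::sd(x) > 0,
                 logical(1))
  if (!is.null(val_features)) {
    vf <- as.data.frame(val_features)[, names(tf), drop = FALSE]
    keep <- keep & vapply(vf, function(x) all(is.finite(x)), logical(1))
  }
  tf <- tf[, keep, drop = FALSE]
  mu <- vapply(tf, mean, numeric(1))
  sd_ <- vapply(tf, stats::sd, numeric(1))
  zs <- function(df) as.data.frame(scale(as.matrix(df[, names(tf), drop = FALSE]),
                                         center = mu, scale = sd_))
  list(train = zs(tf),
       val = if (!is.null(val_features)) zs(as.data.frame(val_features)) else NULL,
       mu = mu, sd = sd_, dropped = names(keep)[!keep])
}

#' Train and validate the seven prognostic models
#'
#' Builds the single-block models -- VASARI (univariate screen, correlation
#' elimination, backward elimination), radiomics (same chain on Z-scored
#' features with training parameters transferred) and clinical (all
#' covariates entered) -- then the stacked combinations of their prognostic
#' indexes: VASARI+radiomics, VASARI+clinical, radiomics+clinical, and the
#' fully integrated model. Validation reports Harrell's C per model on both
#' cohorts, plus calibration slope, joint misspecification test and the
#' 75th-percentile risk-group split for the integrated model.
#'
#' @param blocks list with per-cohort data: `vasari_train`, `vasari_val`
#'   (encoded design matrices), `radiomics_train`, `radiomics_val` (raw
#'   feature frames), `clinical_train`, `clinical_val` (see
#'   [clinical_model()]).
#' @param surv_train,surv_val survival data frames.
#' @param screen_alpha,cor_threshold,backward_alpha,percentile chain
#'   parameters.
#' @param n_boot bootstrap resamples for C-index CIs.
#' @param seed seed for the bootstrap.
#' @return Object of class `gx_prognostic_result`.
#' @export
prognostic_workflow <- function(blocks, surv_train, surv_val,
                                screen_alpha = 0.2, cor_threshold = 0.85,
                                backward_alpha = 0.2, percentile = 75,
                                n_boot = 200L, seed = 1L) {
  rad <- prepare_radiomics_block(blocks$radiomics_train, blocks$radiomics_val)
  m_vasari <- train_prognostic_block(blocks$vasari_train, surv_train,
                                     screen_alpha, cor_threshold,
                                     backward_alpha)
  m_radiomics <- train_prognostic_block(rad$train, surv_train, screen_alpha,
                                        cor_threshold, backward_alpha)
  m_clinical <- clinical_model(blocks$clinical_train, surv_train)

  clin_design <- function(cl) data.frame(
    sex_male = as.numeric(cl$sex == "male"),
    surgery_resection = as.numeric(cl$surgery %in% c("resection", "debulking")),
    age_over_70 = if ("age_over_70" %in% names(cl)) as.numeric(cl$age_over_70)
      else as.numeric(cl$age > 70),
    adjuvant_non_stupp = as.numeric(cl$adjuvant != "STUPP"),
    mgmt_methylated = as.numeric(cl$mgmt_methylated))

  pis <- list(
    train = data.frame(
      vasari = compute_pi(m_vasari, blocks$vasari_train),
      radiomics = compute_pi(m_radiomics, rad$train),
      clinical = compute_pi(m_clinical, clin_design(blocks$clinical_train))),
    val = data.frame(
      vasari = compute_pi(m_vasari, blocks$vasari_val),
      radiomics = compute_pi(m_radiomics, rad$val),
      clinical = compute_pi(m_clinical, clin_design(blocks$clinical_val))))

  combos <- list(model4 = c("vasari", "radiomics"),
                 model5 = c("vasari", "clinical"),
                 model6 = c("radiomics", "clinical"),
                 model7 = c("vasari", "radiomics", "clinical"))
  # degenerate (empty-model) components cannot enter a stack; drop them, and
  # if a single component remains use it directly (unit coefficient)
  stacked <- lapply(combos, function(cols) {
    live <- cols[vapply(pis$train[cols], function(p)
      stats::sd(p, na.rm = TRUE) > 0, logical(1))]
    if (length(live) >= 2) {
      tryCatch(stack_pi(pis$train[, live, drop = FALSE], surv_train),
               error = function(e) {
                 warning("stacking failed (", conditionMessage(e),
                         "); using the first live component")
                 cox_model(stats::setNames(1, live[1]))
               })
    } else if (length(live) == 1) {
      warning("only one non-degenerate component for ",
              paste(cols, collapse = "+"), "; passing its PI through")
      cox_model(stats::setNames(1, live))
    } else {
      warning("all components degenerate for ", paste(cols, collapse = "+"))
      cox_model(stats::setNames(0, cols[1]))
    }
  })

  model_pis <- function(split) {
    p <- pis[[split]]
    out <- list(model1 = p$vasari, model2 = p$radiomics, model3 = p$clinical)
    for (nm in names(combos))
      out[[nm]] <- compute_pi(stacked[[nm]], p[, combos[[nm]], drop = FALSE])
    out
  }
  pt <- model_pis("train"); pv <- model_pis("val")
  cindex <- do.call(rbind, lapply(names(pt), function(nm) {
    ct <- harrell_c(pt[[nm]], surv_train, n_boot, seed = derive_seed(seed, 1L))
    cv <- harrell_c(pv[[nm]], surv_val, n_boot, seed = derive_seed(seed, 2L))
    data.frame(model = nm,
               c_train = ct$c_index, c_train_lo = ct$ci_lower,
               c_train_hi = ct$ci_upper,
               c_val = cv$c_index, c_val_lo = cv$ci_lower,
               c_val_hi = cv$ci_upper)
  }))

  na_diag <- list(slope = NA_real_, se = NA_real_, statistic = NA_real_,
                  p = NA_real_, df = NA_real_)
  calib <- tryCatch(calibration_slope(pv$model7, surv_val),
                    error = function(e) { warning(conditionMessage(e)); na_diag })
  missp <- tryCatch(
    misspecification_test(pis$val[, combos$model7, drop = FALSE],
                          stacked$model7, surv_val),
    error = function(e) { warning(conditionMessage(e)); na_diag })
  km <- km_split(pt$model7, surv_train, pv$model7, surv_val, percentile)

  structure(list(models = c(list(model1 = m_vasari, model2 = m_radiomics,
                                 model3 = m_clinical), stacked),
                 component_pis = pis, model_pis = list(train = pt, val = pv),
                 c_index = cindex, calibration = calib,
                 misspecification = missp, km = km,
                 radiomics_prep = rad[c("mu", "sd", "dropped")]),
            class = "gx_prognostic_result")
}

#' @export
print.gx_prognostic_result <- function(x, ...) {
  cat("<gx_prognostic_result>\n")
  print(transform(x$c_index, c_train = round(c_train, 3),
                  c_val = round(c_val, 3))[, c("model", "c_train", "c_val")])
  cat(sprintf("  calibration slope (model7, validation): %.3f (p[slope=1] %.3f)\n",
              x$calibration$slope, x$calibration$p))
  cat(sprintf("  misspecification joint p: %.3f\n", x$misspecification$p))
  invisible(x)
}

# One predictive arm (VASARI or radiomics features) for one marker.
predictive_arm <- function(X_train, y_train, X_val, families, cfg, seed) {
  sel <- eliminate_correlated_by_auc(X_train, y_train, cfg$cor_threshold)
  Xt <- X_train[, sel, drop = FALSE]
  Xv <- X_val[, sel, drop = FALSE]
  mu <- vapply(Xt, mean, numeric(1)); sd_ <- vapply(Xt, stats::sd, numeric(1))
  sd_[sd_ == 0] <- 1
  Xt <- as.data.frame(scale(as.matrix(Xt), mu, sd_))
  Xv <- as.data.frame(scale(as.matrix(Xv), mu, sd_))

  split0 <- stratified_split(y_train, cfg$split_ratio, derive_seed(seed, 3L))
  imp <- rf_importance_rank(Xt[split0$train, , drop = FALSE],
                            y_train[split0$train],
                            n_iter = cfg$n_iter_importance, seed =
                              derive_seed(seed, 4L), top_k = cfg$top_k)
  feats <- imp$top
  search <- model_search(Xt[split0$train, feats, drop = FALSE],
                         y_train[split0$train],
                         Xt[split0$test, feats, drop = FALSE],
                         y_train[split0$test],
                         families = families, n_iter = cfg$n_iter_search,
                         seed = derive_seed(seed, 5L))
  top5 <- utils::head(search, 5L)
  if (isTRUE(cfg$reselect)) {
    aucm <- matrix(NA_real_, length(top5), cfg$n_repeats)
    for (r in seq_len(cfg$n_repeats)) {
      sp <- stratified_split(y_train, cfg$split_ratio,
                             derive_seed(seed, 600L + r))
      imp_r <- rf_importance_rank(Xt[sp$train, , drop = FALSE],
                                  y_train[sp$train],
                                  n_iter = cfg$n_iter_importance,
                                  seed = derive_seed(seed, 700L + r),
                                  top_k = cfg$top_k)
      for (m in seq_along(top5)) {
        cand <- top5[[m]]
        aucm[m, r] <- tryCatch({
          fit <- train_candidate(cand$family, cand$params,
                                 Xt[sp$train, imp_r$top, drop = FALSE],
                                 y_train[sp$train],
                                 seed = derive_seed(seed, 800L + r * 17L + m))
          auc_score(y_train[sp$test],
                    predict_candidate(fit, cand$family,
                                      Xt[sp$test, imp_r$top, drop = FALSE]))
        }, error = function(e) NA_real_)
      }
    }
    means <- rowMeans(aucm, na.rm = TRUE)
    best <- top5[[which.max(means)]]
    eval_summary <- data.frame(candidate = seq_along(top5),
                               family = vapply(top5, `[[`, "", "family"),
                               mean_auc = means,
                               sd_auc = apply(aucm, 1, stats::sd, na.rm = TRUE))
  } else {
    ev <- repeated_split_eval(top5, Xt[, feats, drop = FALSE], y_train,
                              n_repeats = cfg$n_repeats,
                              ratio = cfg$split_ratio,
                              seed = derive_seed(seed, 6L))
    best <- ev$best
    eval_summary <- ev$summary
  }
  final_fit <- train_candidate(best$family, best$params,
                               Xt[, feats, drop = FALSE], y_train,
                               seed = derive_seed(seed, 9L))
  list(selected = feats, best = best, eval = eval_summary,
       probs_val = predict_candidate(final_fit, best$family,
                                     Xv[, feats, drop = FALSE]),
       probs_train = predict_candidate(final_fit, best$family,
                                       Xt[, feats, drop = FALSE]),
       search_top_auc = search[[1]]$auc)
}

#' Predictive-model configuration defaults
#'
#' @param n_iter_importance forest fits in the importance stage.
#' @param n_iter_search randomized search candidates.
#' @param n_repeats repeated splits for the top 5.
#' @param top_k features kept from the importance ranking.
#' @param split_ratio stratified train fraction.
#' @param cor_threshold Spearman elimination threshold.
#' @param n_boot bootstrap AUC iterations.
#' @param reselect re-run the importance selection on every repeated split
#'   (set `FALSE` to freeze the first selection).
#' @return Named list.
#' @export
predictive_config <- function(n_iter_importance = 1000L, n_iter_search = 1000L,
                              n_repeats = 10L, top_k = 20L, split_ratio = 0.7,
                              cor_threshold = 0.85, n_boot = 100L,
                              reselect = TRUE) {
  list(n_iter_importance = n_iter_importance, n_iter_search = n_iter_search,
       n_repeats = n_repeats, top_k = top_k, split_ratio = split_ratio,
       cor_threshold = cor_threshold, n_boot = n_boot, reselect = reselect)
}

#' Train and externally validate one molecular-marker predictor
#'
#' Runs the VASARI arm and the radiomics arm through correlation elimination
#' (lower univariate AUC removed), Z-score normalisation frozen on the
#' modelling cohort, a 70/30 stratified split, cumulative random-forest
#' importance selection of the top features, randomized model search over
#' the learner families, repeated-split evaluation of the top 5, and a final
#' refit on the full modelling cohort. Validation-cohort probabilities of
#' the two arms are ensembled by averaging; AUCs carry bootstrap CIs.
#' Patients with a missing marker label are excluded up front. For MGMT the
#' VASARI arm is pinned to logistic regression.
#'
#' @param marker one of `"MGMT"`, `"EGFR"`, `"IDH1"`.
#' @param vasari_train,vasari_val encoded VASARI design matrices.
#' @param radiomics_train,radiomics_val radiomics feature frames.
#' @param labels_train,labels_val 0/1/NA marker labels.
#' @param cfg a [predictive_config()].
#' @param seed master seed.
#' @return Object of class `gx_predictive_result`.
#' @export
predictive_workflow <- function(marker, vasari_train, vasari_val,
                                radiomics_train, radiomics_val,
                                labels_train, labels_val,
                                cfg = predictive_config(), seed = 1L) {
  keep_t <- !is.na(labels_train)
  keep_v <- !is.na(labels_val)
  y_t <- as.integer(labels_train[keep_t])
  y_v <- as.integer(labels_val[keep_v])
  rad <- prepare_radiomics_block(radiomics_train[keep_t, , drop = FALSE],
                                 radiomics_val[keep_v, , drop = FALSE])
  fam_all <- c("xgboost", "random_forest", "logistic")
  fam_vasari <- if (marker == "MGMT") "logistic" else fam_all
  arm_v <- predictive_arm(vasari_train[keep_t, , drop = FALSE], y_t,
                          vasari_val[keep_v, , drop = FALSE],
                          fam_vasari, cfg, derive_seed(seed, 101L))
  arm_r <- predictive_arm(rad$train, y_t, rad$val, fam_all, cfg,
                          derive_seed(seed, 102L))
  probs_ens <- ensemble_average(arm_v$probs_val, arm_r$probs_val)
  ci <- function(p, k) tryCatch(
    bootstrap_auc_ci(y_v, p, cfg$n_boot, seed = derive_seed(seed, 200L + k)),
    error = function(e) {
      message(marker, ": validation AUC undefined (", conditionMessage(e), ")")
      list(auc = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
           n_boot = cfg$n_boot, redraws = NA_integer_)
    })
  structure(list(marker = marker, n_train = sum(keep_t), n_val = sum(keep_v),
                 vasari = arm_v, radiomics = arm_r,
                 val_auc = list(vasari = ci(arm_v$probs_val, 1L),
                                radiomics = ci(arm_r$probs_val, 2L),
                                ensemble = ci(probs_ens, 3L)),
                 probs_val = list(vasari = arm_v$probs_val,
                                  radiomics = arm_r$probs_val,
                                  ensemble = probs_ens),
                 y_val = y_v),
            class = "gx_predictive_result")
}

#' @export
print.gx_predictive_result <- function(x, ...) {
  cat(sprintf("<gx_predictive_result %s  (n_train=%d, n_val=%d)>\n",
              x$marker, x$n_train, x$n_val))
  for (nm in names(x$val_auc)) {
    a <- x$val_auc[[nm]]
    cat(sprintf("  %-9s validation AUC %.3f (95%% CI %.3f-%.3f)\n", nm,
                a$auc, a$ci_lower, a$ci_upper))
  }
  invisible(x)
}
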