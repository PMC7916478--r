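as_surv <- function(surv) {
  if (inherits(surv, "Surv")) return(surv)
  survival::Surv(surv$time, surv$event)
}

#' Univariate Cox screening of candidate features
#'
#' Fits one single-covariate Cox model per feature and keeps those whose Wald
#' p-value is at most `alpha` (the conventional liberal screening threshold
#' of 0.2 by default). Constant features carry no information and are never
#' selected; features whose fit does not converge are dropped and logged.
#'
#' @param X numeric data frame/matrix of candidate features.
#' @param surv data frame with `time` and `event` columns (or a `Surv`).
#' @param alpha inclusion threshold on the Wald p-value (inclusive).
#' @return Character vector of selected feature ids, with attribute
#'   `"screen"` (data frame of per-feature coefficient, HR, p) and
#'   `"dropped"` (non-convergent features).
#' @export
univariate_cox_screen <- function(X, surv, alpha = 0.2) {
  X <- as.data.frame(X)
  y <- as_surv(surv)
  if (sum(y[, "status"]) < 1) stop("need at least one event", call. = FALSE)
  res <- lapply(names(X), function(nm) {
    x <- X[[nm]]
    if (stats::sd(x) == 0) return(data.frame(feature = nm, beta = NA, hr = NA,
                                             p = NA, status = "constant"))
    fit <- tryCatch({
      f <- survival::coxph(y ~ x, ties = "efron")
      s <- summary(f)
      data.frame(feature = nm, beta = unname(stats::coef(f)),
                 hr = unname(exp(stats::coef(f))),
                 p = s$coefficients[1, "Pr(>|z|)"], status = "ok")
    }, warning = function(w) data.frame(feature = nm, beta = NA, hr = NA,
                                        p = NA, status = "nonconvergent"),
       error = function(e) data.frame(feature = nm, beta = NA, hr = NA,
                                      p = NA, status = "nonconvergent"))
    fit
  })
  tab <- do.call(rbind, res)
  sel <- tab$feature[tab$status == "ok" & tab$p <= alpha]
  structure(sel, screen = tab,
            dropped = tab$feature[tab$status == "nonconvergent"])
}

#' Eliminate highly rank-correlated features
#'
#' Greedy elimination of feature pairs whose absolute Spearman rank
#' correlation strictly exceeds `threshold` (a pair at exactly the threshold
#' is kept). At each step the most correlated remaining pair is resolved by
#' dropping the lower-priority member: by default the later column; when
#' `priority` is supplied (e.g. univariate Cox p-values, smaller = better),
#' the member with the larger priority value is dropped, ties resolved
#' lexicographically. Deterministic throughout.
#'
#' @param X numeric data frame of features.
#' @param threshold Spearman threshold (strict inequality).
#' @param priority optional named numeric; smaller values survive.
#' @return Character vector of surviving feature ids.
#' @export
eliminate_correlated <- function(X, threshold = 0.85, priority = NULL) {
  X <- as.data.frame(X)
  keep <- names(X)
  if (length(keep) < 2) return(keep)
  cm <- suppressWarnings(stats::cor(X, method = "spearman"))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  repeat {
    sub <- abs(cm[keep, keep, drop = FALSE])
    mx <- max(sub)
    if (mx <= threshold) break
    w <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- keep[w[1]]; b <- keep[w[2]]
    drop_f <- if (!is.null(priority) && !is.na(priority[a]) &&
                  !is.na(priority[b]) && priority[a] != priority[b]) {
      if (priority[a] > priority[b]) a else b
    } else {
      # later column loses; lexicographic on ties of position cannot happen
      if (match(a, names(X)) > match(b, names(X))) a else b
    }
    keep <- setdiff(keep, drop_f)
    if (length(keep) < 2) break
  }
  keep
}

#' Fit a multivariable Cox proportional-hazards model
#'
#' Maximises the Cox partial likelihood with Efron tie handling and wraps the
#' fit as a prognostic model object carrying coefficients, standard errors,
#' Wald p-values, hazard ratios, and the training-mean centering constant of
#' the prognostic index PI = sum(beta * x). Zero-variance features get an
#' exact zero coefficient (they carry no score information). Monotone
#' likelihood (separation) is reported as an error naming the feature.
#'
#' @param X numeric data frame of features.
#' @param surv data frame with `time`/`event` (or `Surv`).
#' @param tag cohort tag stored with the model.
#' @return Object of class `gx_cox_model`.
#' @export
fit_cox <- function(X, surv, tag = "training") {
  X <- as.data.frame(X)
  y <- as_surv(surv)
  # complete cases per model (patients missing a covariate are dropped from
  # this model only)
  ok <- stats::complete.cases(X)
  if (!all(ok)) {
    X <- X[ok, , drop = FALSE]
    y <- y[ok]
  }
  const <- vapply(X, function(c) stats::sd(c) == 0, logical(1))
  Xf <- X[, !const, drop = FALSE]
  if (ncol(Xf) > 0 && sum(y[, "status"]) < ncol(Xf))
    stop("fewer events than features; reduce the feature set", call. = FALSE)
  if (ncol(Xf) == 0) {
    model <- empty_cox_model(tag)
    model$coefficients <- stats::setNames(rep(0, ncol(X)), names(X))
    return(model)
  }
  dat <- cbind(data.frame(.time = y[, "time"], .event = y[, "status"]), Xf)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(Xf)),
                                       collapse = " + ")))
  sep_warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron", x = FALSE),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        sep_warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (!is.null(sep_warn) || any(!is.finite(beta)) || any(abs(beta) > 20)) {
    bad <- names(Xf)[!is.finite(beta) | abs(beta) > 20]
    if (!length(bad)) bad <- names(Xf)[which.max(abs(beta))]
    cond <- structure(
      class = c("gx_separation_error", "error", "condition"),
      list(message = paste("monotone likelihood / separation for feature(s):",
                           paste(bad, collapse = ", ")),
           call = sys.call(-1), features = bad))
    stop(cond)
  }
  names(beta) <- names(Xf)
  s <- summary(fit)$coefficients
  co <- stats::setNames(rep(0, ncol(X)), names(X))
  co[names(beta)] <- beta
  pi_train <- drop(as.matrix(Xf) %*% beta)
  structure(list(
    coefficients = co,
    se = stats::setNames(s[, "se(coef)"], names(beta)),
    p = stats::setNames(s[, "Pr(>|z|)"], names(beta)),
    hr = stats::setNames(exp(beta), names(beta)),
    pi_center = mean(pi_train),
    features = names(X),
    loglik = fit$loglik,
    n = fit$n, n_events = fit$nevent,
    cohort = tag),
    class = "gx_cox_model")
}

empty_cox_model <- function(tag = "training") {
  structure(list(coefficients = stats::setNames(numeric(0), character(0)),
                 se = numeric(0), p = numeric(0), hr = numeric(0),
                 pi_center = 0, features = character(0),
                 loglik = c(NA, NA), n = 0, n_events = 0, cohort = tag),
            class = "gx_cox_model")
}

#' @export
print.gx_cox_model <- function(x, ...) {
  cat(sprintf("<gx_cox_model: %d feature(s), fitted on %s (n=%s, events=%s)>\n",
              length(x$coefficients), x$cohort, x$n, x$n_events))
  if (length(x$p)) {
    tab <- data.frame(coef = x$coefficients[names(x$p)], HR = x$hr,
                      se = x$se, p = x$p)
    print(round(tab, 4))
  }
  invisible(x)
}

#' @export
summary.gx_cox_model <- function(object, ...) {
  print(object)
  invisible(list(coefficients = object$coefficients, se = object$se,
                 p = object$p, hr = object$hr))
}

#' @export
coef.gx_cox_model <- function(object, ...) object$coefficients

#' @export
predict.gx_cox_model <- function(object, newdata, ...) {
  compute_pi(object, newdata)
}

#' Backward elimination on a fitted Cox model
#'
#' Repeatedly removes the feature with the largest Wald p-value while that
#' p-value exceeds `alpha`, refitting after every removal. Deterministic
#' given the input order (ties drop the first of the tied features). If all
#' features are removed an empty model (PI identically 0) is returned with a
#' warning.
#'
#' @param X,surv training data used to (re)fit.
#' @param alpha removal threshold.
#' @param model optional starting model (defaults to the full fit on `X`).
#' @return A reduced `gx_cox_model`.
#' @export
backward_eliminate <- function(X, surv, alpha = 0.2, model = NULL) {
  X <- as.data.frame(X)
  feats <- if (is.null(model)) names(X) else names(model$coefficients)
  repeat {
    if (!length(feats)) {
      warning("all features eliminated; returning empty model (PI = 0)")
      return(empty_cox_model())
    }
    m <- tryCatch(fit_cox(X[, feats, drop = FALSE], surv),
                  gx_separation_error = function(e) e)
    if (inherits(m, "gx_separation_error")) {
      # features with monotone likelihood cannot stay in the model
      bad <- intersect(m$features, feats)
      if (!length(bad)) bad <- feats[length(feats)]
      feats <- setdiff(feats, bad)
      next
    }
    if (!length(m$p)) return(m)     # only degenerate features left
    worst <- max(m$p)
    if (worst <= alpha) return(m)
    drop_f <- names(m$p)[which(m$p == worst)[1]]
    feats <- setdiff(feats, drop_f)
  }
}

#' Prognostic index of patients under a fitted model
#'
#' PI = sum(beta_i x_i), centered by the training mean (the centering
#' constant is part of the model, so PI differences are unaffected by it).
#' Patients missing any model feature receive `NA` and are counted in the
#' `"excluded"` attribute.
#'
#' @param model a `gx_cox_model`.
#' @param X feature data frame containing the model's features.
#' @return Numeric PI vector (length `nrow(X)`), `NA` for excluded patients.
#' @export
compute_pi <- function(model, X) {
  X <- as.data.frame(X)
  if (!length(model$coefficients)) {
    out <- rep(0, nrow(X))
    attr(out, "excluded") <- integer(0)
    return(out)
  }
  need <- names(model$coefficients)
  miss_col <- setdiff(need, names(X))
  if (length(miss_col))
    stop("features absent from data: ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  xm <- as.matrix(X[, need, drop = FALSE])
  pi <- drop(xm %*% model$coefficients) - model$pi_center
  excluded <- which(!stats::complete.cases(X[, need, drop = FALSE]))
  pi[excluded] <- NA_real_
  attr(pi, "excluded") <- excluded
  pi
}

#' Stack component prognostic indexes into a combined Cox model
#'
#' Fits a Cox model using the component PIs (e.g. VASARI, radiomics,
#' clinical) as the only covariates and reports a hazard ratio per component
#' score. Perfectly collinear components are rejected.
#'
#' @param component_pis data frame/matrix of per-patient component PIs
#'   (>= 2 columns).
#' @param surv survival data.
#' @return A `gx_cox_model` over the component scores.
#' @export
stack_pi <- function(component_pis, surv) {
  P <- as.data.frame(component_pis)
  if (ncol(P) < 2) stop("need at least two component PIs to stack", call. = FALSE)
  ok <- stats::complete.cases(P)
  Pc <- P[ok, , drop = FALSE]
  if (qr(scale(as.matrix(Pc), scale = FALSE))$rank < ncol(Pc))
    stop("component PIs are collinear", call. = FALSE)
  y <- as_surv(surv)
  fit_cox(Pc, data.frame(time = y[ok, "time"], event = y[ok, "status"]),
          tag = "training")
}

#' Clinical covariate Cox model
#'
#' All clinical covariates are entered without elimination: sex (male vs
#' female), type of surgery (resection vs biopsy), age group (>70 vs <70),
#' adjuvant regimen (non-STUPP vs STUPP) and MGMT methylation.
#'
#' @param clinical data frame with columns `sex`, `surgery`, `age` (years, or
#'   a precomputed 0/1 `age_over_70`), `adjuvant`, `mgmt_methylated` (0/1).
#' @param surv survival data.
#' @return A `gx_cox_model`.
#' @export
clinical_model <- function(clinical, surv) {
  need <- c("sex", "surgery", "adjuvant", "mgmt_methylated")
  miss <- setdiff(need, names(clinical))
  if (length(miss) || !any(c("age", "age_over_70") %in% names(clinical)))
    stop("clinical table lacks columns: ",
         paste(c(miss, if (!any(c("age", "age_over_70") %in% names(clinical)))
           "age/age_over_70"), collapse = ", "), call. = FALSE)
  X <- data.frame(
    sex_male = as.numeric(clinical$sex == "male"),
    surgery_resection = as.numeric(clinical$surgery %in%
                                     c("resection", "debulking")),
    age_over_70 = if ("age_over_70" %in% names(clinical))
      as.numeric(clinical$age_over_70) else as.numeric(clinical$age > 70),
    adjuvant_non_stupp = as.numeric(clinical$adjuvant != "STUPP"),
    mgmt_methylated = as.numeric(clinical$mgmt_methylated))
  # all covariates are entered; only a monotone-likelihood covariate (possible
  # in very small cohorts) is dropped, with a warning
  repeat {
    m <- tryCatch(fit_cox(X, surv), gx_separation_error = function(e) e)
    if (!inherits(m, "gx_separation_error")) return(m)
    bad <- intersect(m$features, names(X))
    if (!length(bad) || length(bad) >= ncol(X)) stop(m)
    warning("clinical covariate(s) dropped for monotone likelihood: ",
            paste(bad, collapse = ", "))
    X <- X[, setdiff(names(X), bad), drop = FALSE]
  }
}

#' Harrell's concordance index of a prognostic index
#'
#' Censoring-aware concordance over usable pairs (higher PI should fail
#' earlier); tied PIs count 1/2. The confidence interval is a percentile
#' bootstrap over patients.
#'
#' @param pi numeric prognostic index.
#' @param surv survival data.
#' @param n_boot bootstrap resamples for the CI.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return List: `c_index`, `ci_lower`, `ci_upper`, `n`.
#' @export
harrell_c <- function(pi, surv, n_boot = 500L, conf = 0.95, seed = 1L) {
  y <- as_surv(surv)
  ok <- is.finite(pi)
  pi <- pi[ok]; y <- y[ok]
  cc <- survival::concordance(y ~ pi, reverse = TRUE)
  if (is.na(cc$concordance) || sum(cc$count[1:3]) == 0) {
    message("no comparable pairs; concordance undefined")
    return(list(c_index = NA_real_, ci_lower = NA_real_,
                ci_upper = NA_real_, n = length(pi)))
  }
  n <- length(pi)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    cb <- tryCatch(survival::concordance(y[idx] ~ pi[idx], reverse = TRUE),
                   error = function(e) NULL)
    if (is.null(cb)) NA_real_ else cb$concordance
  }, numeric(1)))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, type = 7)
  list(c_index = unname(cc$concordance), ci_lower = unname(qs[1]),
       ci_upper = unname(qs[2]), n = n)
}

#' Calibration slope of a frozen prognostic index on validation data
#'
#' Refits the frozen PI as the sole covariate of a Cox model on the
#' validation cohort. The slope estimate is its coefficient (1 = effect sizes
#' preserved; < 1 = overfitting); the test of slope = 1 is a likelihood-ratio
#' comparison against the model with the PI as a fixed offset. On the
#' training data itself the slope is exactly 1 by the score equation of the
#' original fit.
#'
#' @param pi_val PI computed on the validation cohort with the frozen model.
#' @param surv_val validation survival data.
#' @return List: `slope`, `se`, `statistic`, `p` (test of slope = 1).
#' @export
calibration_slope <- function(pi_val, surv_val) {
  y <- as_surv(surv_val)
  ok <- is.finite(pi_val)
  pi <- pi_val[ok]; y <- y[ok]
  free <- survival::coxph(y ~ pi, ties = "efron")
  fixed <- survival::coxph(y ~ offset(pi), ties = "efron")
  stat <- 2 * (free$loglik[2] - fixed$loglik[1])
  list(slope = unname(stats::coef(free)),
       se = unname(sqrt(stats::vcov(free)[1, 1])),
       statistic = stat,
       p = stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE))
}

#' Joint misspecification test of a frozen signature on validation data
#'
#' Fits the individual features of the signature on the validation cohort
#' with the frozen PI as an offset and performs the joint likelihood-ratio
#' test that all additional coefficients are zero. A small p-value indicates
#' lack of fit of the transferred model.
#'
#' @param X_val validation features (all model features present).
#' @param model the frozen `gx_cox_model`.
#' @param surv_val validation survival data.
#' @return List: `statistic`, `df`, `p`.
#' @export
misspecification_test <- function(X_val, model, surv_val) {
  if (!length(model$coefficients))
    stop("misspecification test undefined for an empty model", call. = FALSE)
  pi <- compute_pi(model, X_val)
  ok <- is.finite(pi)
  y <- as_surv(surv_val)[ok]
  Xf <- as.data.frame(X_val)[ok, names(model$coefficients), drop = FALSE]
  keep <- vapply(Xf, function(c) stats::sd(c) > 0, logical(1))
  Xf <- Xf[, keep, drop = FALSE]
  if (!ncol(Xf)) stop("no non-degenerate features on validation", call. = FALSE)
  dat <- cbind(data.frame(.time = y[, "time"], .event = y[, "status"],
                          .off = pi[ok]), Xf)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~ offset(.off) +",
                                 paste(sprintf("`%s`", names(Xf)),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  stat <- 2 * (fit$loglik[2] - fit$loglik[1])
  df <- sum(!is.na(stats::coef(fit)))
  list(statistic = stat, df = df,
       p = stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE))
}

#' Risk-group split at the training 75th PI percentile
#'
#' The threshold is the stated percentile of the *training* PI distribution,
#' frozen and applied unchanged to validation. Returns observed Kaplan-Meier
#' curves per risk group, model-predicted group-average survival curves
#' (each patient's predicted curve from the PI, averaged over the group),
#' and the log-rank test of the split.
#'
#' @param pi_train,pi_val prognostic indexes (validation may be `NULL`).
#' @param surv_train,surv_val survival data.
#' @param percentile split percentile of the training PI (default 75).
#' @return Object of class `gx_km_split`: `threshold` and per-cohort
#'   `groups`, `logrank_p`, `observed` (survfit), `predicted` (time grid and
#'   group-mean survival).
#' @export
km_split <- function(pi_train, surv_train, pi_val = NULL, surv_val = NULL,
                     percentile = 75) {
  thr <- stats::quantile(pi_train[is.finite(pi_train)], percentile / 100,
                         type = 7, names = FALSE)
  yt <- as_surv(surv_train)
  okt <- is.finite(pi_train)
  base_fit <- survival::coxph(yt[okt] ~ pi, data = data.frame(pi = pi_train[okt]),
                              ties = "efron")
  eval_cohort <- function(pi, surv) {
    ok <- is.finite(pi)
    pi <- pi[ok]
    y <- as_surv(surv)[ok]
    grp <- factor(ifelse(pi > thr, "high", "low"), levels = c("low", "high"))
    if (any(table(grp) == 0)) {
      return(list(groups = grp, logrank_p = NA_real_, observed = NULL,
                  predicted = NULL,
                  note = "a risk group is empty; no test performed"))
    }
    sd <- survival::survdiff(y ~ grp)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    obs <- survival::survfit(y ~ grp)
    pred_fit <- survival::survfit(base_fit, newdata = data.frame(pi = pi))
    sm <- pred_fit$surv      # time x patients
    list(groups = grp, logrank_p = p, observed = obs,
         predicted = list(time = pred_fit$time,
                          low = rowMeans(sm[, grp == "low", drop = FALSE]),
                          high = rowMeans(sm[, grp == "high", drop = FALSE])))
  }
  out <- list(threshold = thr, percentile = percentile,
              train = eval_cohort(pi_train, surv_train))
  if (!is.null(pi_val)) out$val <- eval_cohort(pi_val, surv_val)
  class(out) <- "gx_km_split"
  out
}

#' @export
print.gx_km_split <- function(x, ...) {
  cat(sprintf("<gx_km_split at training P%g = %.4f>\n", x$percentile,
              x$threshold))
  cat(sprintf("  training log-rank p: %.4g\n", x$train$logrank_p))
  if (!is.null(x$val)) cat(sprintf("  validation log-rank p: %.4g\n",
                                   x$val$logrank_p))
  invisible(x)
}

#' Tumor volume from a binary mask
#' @param mask logical array. @param spacing voxel spacing (mm).
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask, spacing) sum(mask) * prod(spacing)

#' Correlation of radiomics features with tumor volume
#'
#' Spearman rank correlation of each feature against tumor volume (mm^3), a
#' check that selected features are not mere volume surrogates.
#'
#' @param X feature data frame.
#' @param volumes numeric tumor volumes (mm^3), e.g. from [mask_volume()].
#' @return Data frame: feature, rs, p.
#' @export
volume_correlation_check <- function(X, volumes) {
  X <- as.data.frame(X)
  res <- lapply(names(X), function(nm) {
    ct <- suppressWarnings(stats::cor.test(X[[nm]], volumes,
                                           method = "spearman", exact = FALSE))
    data.frame(feature = nm, rs = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}

#' Cross-block correlation table
#'
#' Pairwise association between two feature blocks: point-biserial
#' correlation (Pearson on the 0/1 indicator) when exactly one member of the
#' pair is binary, Spearman otherwise. Zero-variance columns are skipped
#' with a note.
#'
#' @param block_a,block_b data frames (e.g. VASARI design matrix vs
#'   radiomics features).
#' @return Data frame: feature_a, feature_b, method, r, p; attribute
#'   `"skipped"` lists zero-variance columns.
#' @export
cross_block_correlation <- function(block_a, block_b) {
  A <- as.data.frame(block_a); B <- as.data.frame(block_b)
  is_bin <- function(x) all(stats::na.omit(x) %in% c(0, 1))
  skipped <- c(names(A)[vapply(A, function(x) stats::sd(x, na.rm = TRUE) == 0,
                               logical(1))],
               names(B)[vapply(B, function(x) stats::sd(x, na.rm = TRUE) == 0,
                               logical(1))])
  rows <- list()
  for (a in setdiff(names(A), skipped)) for (b in setdiff(names(B), skipped)) {
    xa <- A[[a]]; xb <- B[[b]]
    method <- if (xor(is_bin(xa), is_bin(xb))) "point-biserial" else "spearman"
    ct <- suppressWarnings(stats::cor.test(xa, xb,
      method = if (method == "point-biserial") "pearson" else "spearman",
      exact = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(feature_a = a, feature_b = b,
                                            method = method,
                                            r = unname(ct$estimate),
                                            p = ct$p.value)
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Train one feature-block prognostic model
#'
#' The full single-block chain: univariate Cox screen, Spearman correlation
#' elimination (survivor = smaller univariate p), multivariable fit with
#' backward elimination.
#'
#' @param X block features. @param surv survival data.
#' @param screen_alpha,cor_threshold,backward_alpha chain parameters.
#' @param screen apply the univariate screen (the clinical block enters all
#'   features without screening).
#' @return A `gx_cox_model`.
#' @export
train_prognostic_block <- function(X, surv, screen_alpha = 0.2,
                                   cor_threshold = 0.85,
                                   backward_alpha = 0.2, screen = TRUE) {
  X <- as.data.frame(X)
  if (screen) {
    sel <- univariate_cox_screen(X, surv, screen_alpha)
    tab <- attr(sel, "screen")
    if (!length(sel)) {
      warning("no features pass the univariate screen; empty model")
      return(empty_cox_model())
    }
    prio <- stats::setNames(tab$p, tab$feature)
    keep <- eliminate_correlated(X[, sel, drop = FALSE], cor_threshold,
                                 priority = prio)
    # a multivariable fit needs fewer covariates than events: cap the
    # candidate list at events - 1, best univariate p first
    n_events <- sum(as_surv(surv)[, "status"])
    if (length(keep) >= n_events)
      keep <- keep[order(prio[keep])][seq_len(max(1L, n_events - 1L))]
  } else keep <- names(X)
  backward_eliminate(X[, keep, drop = FALSE], surv, alpha = backward_alpha)
}
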