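#' Demo pipeline configuration
#'
#' A complete configuration for an end-to-end synthetic run: cohort sizes,
#' phantom field of view, preprocessing toggles, filter bank, model-chain
#' parameters and search budgets. Every stochastic stage derives its seed
#' from the single master `seed`.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed.
#' @param n_train,n_val cohort sizes.
#' @param fov_mm phantom field of view (mm).
#' @param log_sigmas_mm LoG scales for extraction.
#' @param n_iter_importance,n_iter_search,n_repeats predictive search budgets.
#' @param markers markers to model.
#' @return Nested configuration list (YAML-serialisable).
#' @export
demo_config <- function(out_dir = tempfile("gliomix_run_"), seed = 1L,
                        n_train = 120L, n_val = 40L,
                        fov_mm = c(48, 48, 28),
                        log_sigmas_mm = c(2, 3),
                        n_iter_importance = 50L, n_iter_search = 60L,
                        n_repeats = 5L, markers = c("EGFR", "MGMT")) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = c("simulate", "preprocess", "extract", "prognostic",
               "predictive", "report"),
    simulate = list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                    images = TRUE, fov_mm = fov_mm,
                    missing_marker_frac = 0.05),
    preprocess = list(resample = TRUE, target_spacing = NULL,
                      bias_correct = TRUE, equalize = TRUE),
    extract = list(log_sigmas_mm = log_sigmas_mm, wavelet = TRUE,
                   n_bins = 16L),
    prognostic = list(screen_alpha = 0.2, cor_threshold = 0.85,
                      backward_alpha = 0.2, percentile = 75, n_boot = 100L),
    predictive = list(markers = markers,
                      n_iter_importance = as.integer(n_iter_importance),
                      n_iter_search = as.integer(n_iter_search),
                      n_repeats = as.integer(n_repeats), top_k = 20L,
                      split_ratio = 0.7, cor_threshold = 0.85,
                      n_boot = 50L, reselect = FALSE))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$out_dir), !is.null(cfg$seed))
  cfg
}

config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

# Preprocess both cohorts: per-image resample/bias/equalize, then Z-score
# parameters frozen on the training cohort and transferred.
preprocess_cohorts <- function(cohorts, cfg) {
  target <- cfg$target_spacing
  if (is.null(target)) target <- spacing_mode(cohorts$train$spacings[-1])
  pc_partial <- preprocess_config(target_spacing = target,
                                  resample = cfg$resample,
                                  bias_correct = cfg$bias_correct,
                                  equalize = cfg$equalize, zscore = NULL)
  run_partial <- function(co) lapply(co$patients, function(p) {
    v <- p$volumes
    rs_mask <- function(mask, img_from, img_to) {
      mi <- gx_image(array(as.numeric(mask), dim(mask)), img_from$spacing)
      array(resample_volume(mi, img_to$spacing)$values >= 0.5,
            dim(img_to$values))
    }
    t1 <- preprocess_pipeline(v$t1, pc_partial)
    t2 <- preprocess_pipeline(v$t2, pc_partial)
    list(t1 = t1, t2 = t2,
         t1_mask = rs_mask(v$t1_mask, v$t1, t1),
         t2_mask = rs_mask(v$t2_mask, v$t2, t2))
  })
  train_p <- run_partial(cohorts$train)
  val_p <- run_partial(cohorts$val)
  zs <- list(
    T1Gd = estimate_zscore_params(lapply(train_p, `[[`, "t1")),
    T2 = estimate_zscore_params(lapply(train_p, `[[`, "t2")))
  apply_z <- function(ps) lapply(ps, function(p) {
    p$t1 <- apply_zscore(p$t1, zs$T1Gd)
    p$t2 <- apply_zscore(p$t2, zs$T2)
    p
  })
  list(train = apply_z(train_p), val = apply_z(val_p), zscore = zs,
       target_spacing = target)
}

extract_cohort <- function(processed, config) {
  rows <- lapply(processed, function(p) {
    fv <- extract_features(p$t1, p$t2,
                           list(T1Gd = p$t1_mask, T2 = p$t2_mask), config)
    as.data.frame(as.list(fv), check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in order: `simulate` (synthetic cohorts
#' with ground truth), `preprocess` (geometric/intensity normalisation with
#' training-frozen Z-score transfer), `extract` (radiomics features, cached
#' by configuration hash since extraction dominates runtime), `prognostic`
#' (Models 1-7 with external-validation diagnostics), `predictive`
#' (per-marker classification) and `report` (plots + tables). All CSV/JSON
#' artifacts are written under `config$out_dir` and hashed into the run
#' manifest; two runs with the same configuration produce identical hashes.
#'
#' @param config configuration list (see [demo_config()]) or a YAML path.
#' @return Invisible list with all stage results plus the `manifest`.
#' @export
gx_run <- function(config = demo_config()) {
  if (is.character(config)) config <- read_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  res <- list(config = config)

  if ("simulate" %in% stages) {
    sim <- config$simulate
    gt <- ground_truth(seed = config$seed)
    res$cohorts <- generate_cohorts(
      n_train = sim$n_train, n_val = sim$n_val, gt = gt,
      images = isTRUE(sim$images),
      image_params = list(fov_mm = unlist(sim$fov_mm)),
      missing_marker_frac = sim$missing_marker_frac,
      out_dir = file.path(out_dir, "cohorts"))
  }

  feat_cfg <- filter_bank_config(
    log_sigmas_mm = unlist(config$extract$log_sigmas_mm),
    wavelet = isTRUE(config$extract$wavelet),
    n_bins = config$extract$n_bins)

  if (all(c("preprocess", "extract") %in% stages)) {
    cache_key <- config_hash(config[c("seed", "simulate", "preprocess",
                                      "extract")])
    cache_file <- file.path(out_dir, "extract_cache.json")
    tr_csv <- file.path(out_dir, "train_features.csv")
    va_csv <- file.path(out_dir, "val_features.csv")
    cached <- file.exists(cache_file) && file.exists(tr_csv) &&
      identical(read_json_file(cache_file)$key, cache_key)
    if (cached) {
      res$features <- list(
        train = utils::read.csv(tr_csv, check.names = FALSE),
        val = utils::read.csv(va_csv, check.names = FALSE))
    } else {
      prep <- preprocess_cohorts(res$cohorts, config$preprocess)
      res$preprocess <- prep[c("zscore", "target_spacing")]
      res$features <- list(train = extract_cohort(prep$train, feat_cfg),
                           val = extract_cohort(prep$val, feat_cfg))
      utils::write.csv(cbind(patient_id = res$cohorts$train$ids,
                             res$features$train), tr_csv, row.names = FALSE)
      utils::write.csv(cbind(patient_id = res$cohorts$val$ids,
                             res$features$val), va_csv, row.names = FALSE)
      write_json_file(list(key = cache_key), cache_file)
    }
    if ("patient_id" %in% names(res$features$train)) {
      res$features$train$patient_id <- NULL
      res$features$val$patient_id <- NULL
    }
  }

  co <- res$cohorts
  clin <- function(tag) cbind(co[[tag]]$clinical[-1],
                              mgmt_methylated = co[[tag]]$markers$MGMT)

  if ("prognostic" %in% stages) {
    pg <- config$prognostic
    blocks <- list(
      vasari_train = encode_vasari(recode_vasari(co$train$vasari)),
      vasari_val = encode_vasari(recode_vasari(co$val$vasari)),
      radiomics_train = res$features$train,
      radiomics_val = res$features$val,
      clinical_train = clin("train"), clinical_val = clin("val"))
    res$prognostic <- prognostic_workflow(
      blocks, co$train$survival[-1], co$val$survival[-1],
      screen_alpha = pg$screen_alpha, cor_threshold = pg$cor_threshold,
      backward_alpha = pg$backward_alpha, percentile = pg$percentile,
      n_boot = pg$n_boot, seed = derive_seed(config$seed, 31L))
    utils::write.csv(res$prognostic$c_index,
                     file.path(out_dir, "prognostic_c_index.csv"),
                     row.names = FALSE)
    write_json_file(list(
      models = lapply(res$prognostic$models, function(m)
        list(features = names(m$coefficients),
             beta = as.list(m$coefficients), pi_center = m$pi_center)),
      calibration = res$prognostic$calibration[c("slope", "p")],
      misspecification = res$prognostic$misspecification[c("statistic", "df",
                                                           "p")],
      km_threshold = res$prognostic$km$threshold,
      km_logrank_p = list(train = res$prognostic$km$train$logrank_p,
                          val = res$prognostic$km$val$logrank_p)),
      file.path(out_dir, "prognostic_models.json"))
  }

  if ("predictive" %in% stages) {
    pd <- config$predictive
    cfg <- predictive_config(
      n_iter_importance = pd$n_iter_importance,
      n_iter_search = pd$n_iter_search, n_repeats = pd$n_repeats,
      top_k = pd$top_k, split_ratio = pd$split_ratio,
      cor_threshold = pd$cor_threshold, n_boot = pd$n_boot,
      reselect = isTRUE(pd$reselect))
    vt <- encode_vasari(recode_vasari(co$train$vasari))
    vv <- encode_vasari(recode_vasari(co$val$vasari))
    res$predictive <- list()
    for (mk in pd$markers) {
      pr <- tryCatch(
        predictive_workflow(mk, vt, vv, res$features$train,
                            res$features$val,
                            co$train$markers[[mk]], co$val$markers[[mk]],
                            cfg, seed = derive_seed(config$seed, 41L)),
        error = function(e) {
          message(mk, ": predictive modelling skipped (",
                  conditionMessage(e), ")")
          NULL
        })
      if (is.null(pr)) next
      res$predictive[[mk]] <- pr
      write_json_file(list(
        marker = mk, n_train = pr$n_train, n_val = pr$n_val,
        selected_vasari = pr$vasari$selected,
        selected_radiomics = pr$radiomics$selected,
        best_family = list(vasari = pr$vasari$best$family,
                           radiomics = pr$radiomics$best$family),
        val_auc = lapply(pr$val_auc, function(a)
          a[c("auc", "ci_lower", "ci_upper")])),
        file.path(out_dir, sprintf("predictive_%s.json", mk)))
    }
  }

  if ("report" %in% stages) res$report <- gx_report(res, out_dir)

  arts <- sort(list.files(out_dir, pattern = "\\.(csv|json)$",
                          recursive = TRUE, full.names = TRUE))
  arts <- arts[basename(arts) != "run_manifest.json"]
  hashes <- tools::md5sum(arts)
  names(hashes) <- sub(paste0("^", gsub("([\\^$.|?*+(){}\\[\\]])", "\\\\\\1",
                                        out_dir), "/?"), "", names(hashes))
  res$manifest <- list(seed = config$seed, stages = stages,
                       config_hash = config_hash(config[setdiff(names(config),
                                                                "out_dir")]),
                       artifact_hashes = as.list(hashes),
                       package_version =
                         as.character(utils::packageVersion("gliomix")))
  write_json_file(res$manifest, file.path(out_dir, "run_manifest.json"))
  invisible(res)
}

# ROC curve points (FPR, TPR) over all thresholds.
roc_points <- function(y, probs) {
  ord <- order(-probs)
  y <- y[ord]
  tpr <- c(0, cumsum(y == 1) / sum(y == 1))
  fpr <- c(0, cumsum(y == 0) / sum(y == 0))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Render the analysis report
#'
#' Writes the figure set of a completed run: the C-index forest plot across
#' Models 1-7 (training and validation with 95% CIs), Kaplan-Meier curves of
#' the integrated model's risk groups (observed solid, model-predicted
#' dashed), and per-marker AUC bars and ROC curves, plus the underlying CSV
#' tables. Sections whose artifacts are missing are skipped with a notice.
#'
#' @param res result list from [gx_run()].
#' @param out_dir output directory.
#' @return Character vector of written files, invisibly.
#' @export
gx_report <- function(res, out_dir) {
  rep_dir <- file.path(out_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  pdf_file <- file.path(rep_dir, "report.pdf")
  grDevices::pdf(pdf_file, width = 7, height = 5)
  on.exit(grDevices::dev.off())

  if (!is.null(res$prognostic)) {
    ci <- res$prognostic$c_index
    k <- nrow(ci)
    graphics::plot(NULL, xlim = c(0.3, 1), ylim = c(0.5, k + 0.5),
                   yaxt = "n", xlab = "Harrell's C-index", ylab = "",
                   main = "Prognostic models: discrimination")
    graphics::axis(2, at = rev(seq_len(k)), labels = ci$model, las = 1)
    for (i in seq_len(k)) {
      yy <- k - i + 1
      graphics::segments(ci$c_train_lo[i], yy + 0.12, ci$c_train_hi[i],
                         yy + 0.12, col = "steelblue")
      graphics::points(ci$c_train[i], yy + 0.12, pch = 16, col = "steelblue")
      graphics::segments(ci$c_val_lo[i], yy - 0.12, ci$c_val_hi[i], yy - 0.12,
                         col = "firebrick")
      graphics::points(ci$c_val[i], yy - 0.12, pch = 17, col = "firebrick")
    }
    graphics::abline(v = 0.5, lty = 3)
    graphics::legend("bottomright", legend = c("training", "validation"),
                     col = c("steelblue", "firebrick"), pch = c(16, 17),
                     bty = "n")

    km <- res$prognostic$km
    for (split in intersect(c("train", "val"), names(km))) {
      part <- km[[split]]
      if (is.null(part$observed)) next
      graphics::plot(part$observed, col = c("blue", "red"), lwd = 2,
                     xlab = "Months", ylab = "Survival probability",
                     main = sprintf("Risk groups (%s), log-rank p = %.2g",
                                    split, part$logrank_p))
      graphics::lines(part$predicted$time, part$predicted$low, col = "blue",
                      lty = 2)
      graphics::lines(part$predicted$time, part$predicted$high, col = "red",
                      lty = 2)
      graphics::legend("topright",
                       legend = c("low risk (obs)", "high risk (obs)",
                                  "predicted"),
                       col = c("blue", "red", "black"),
                       lty = c(1, 1, 2), bty = "n")
    }
  } else message("no prognostic artifacts; section skipped")

  if (!is.null(res$predictive) && length(res$predictive)) {
    for (mk in names(res$predictive)) {
      pr <- res$predictive[[mk]]
      aucs <- vapply(pr$val_auc, `[[`, 0, "auc")
      lo <- vapply(pr$val_auc, `[[`, 0, "ci_lower")
      hi <- vapply(pr$val_auc, `[[`, 0, "ci_upper")
      if (anyNA(aucs) || length(unique(pr$y_val)) < 2) {
        message(mk, ": validation AUC undefined; section skipped")
        next
      }
      bp <- graphics::barplot(aucs, ylim = c(0, 1), col = "grey80",
                              main = sprintf("%s: validation AUC", mk),
                              ylab = "AUC")
      graphics::arrows(bp, lo, bp, hi, angle = 90, code = 3, length = 0.05)
      graphics::abline(h = 0.5, lty = 3)
      rc <- roc_points(pr$y_val, pr$probs_val$ensemble)
      graphics::plot(rc$fpr, rc$tpr, type = "s", lwd = 2,
                     xlab = "False positive rate", ylab = "True positive rate",
                     main = sprintf("%s: ensemble ROC (validation)", mk))
      graphics::abline(0, 1, lty = 3)
      roc_csv <- file.path(rep_dir, sprintf("roc_%s.csv", mk))
      utils::write.csv(rc, roc_csv, row.names = FALSE)
      written <- c(written, roc_csv)
    }
  } else message("no predictive artifacts; prognostic-only report")

  invisible(c(written, pdf_file))
}
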