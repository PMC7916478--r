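#' Scanner acquisition profile
#'
#' Describes one scanner/protocol combination used to synthesise a cohort:
#' in-plane pixel spacing, slice thickness, the amplitude of the smooth
#' multiplicative intensity bias field and the additive noise level. Cohorts
#' are drawn from mixtures of profiles to emulate multi-centre heterogeneity
#' in voxel geometry and image quality.
#'
#' @param pixel_spacing_mm length-2 positive in-plane spacing (mm).
#' @param slice_thickness_mm positive through-plane spacing (mm).
#' @param bias_amplitude nonnegative relative amplitude of the multiplicative
#'   bias field; must be < 1.
#' @param noise_sd nonnegative standard deviation of additive Gaussian noise,
#'   on the scale of the tissue levels (which are O(1)).
#' @return An object of class `gx_scanner_profile`.
#' @export
scanner_profile <- function(pixel_spacing_mm = c(0.9, 0.9),
                            slice_thickness_mm = 5.5,
                            bias_amplitude = 0.2,
                            noise_sd = 0.02) {
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (any(pixel_spacing_mm <= 0) || slice_thickness_mm <= 0)
    stop("spacing and slice thickness must be strictly positive", call. = FALSE)
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("bias_amplitude must be in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 bias_amplitude = bias_amplitude,
                 noise_sd = noise_sd),
            class = "gx_scanner_profile")
}

#' Ground truth of a synthetic cohort
#'
#' Records the generating parameters alongside every synthetic cohort:
#' log-hazard coefficients over named latent features, per-marker logistic
#' coefficients, the exponential baseline hazard and censoring rates, and the
#' master seed. An identical ground truth (and profiles) regenerates an
#' identical cohort, which is what makes parameter-recovery tests possible.
#'
#' @param beta_surv named numeric vector of log-hazard coefficients.
#' @param beta_marker named list of named numeric vectors, one per marker in
#'   `MGMT`, `EGFR`, `IDH1`; each vector may carry an `(Intercept)` entry.
#' @param baseline_hazard_rate positive exponential baseline hazard
#'   (events/month). The default puts the median survival of a baseline
#'   patient at 12 months.
#' @param censor_rate positive rate of the independent exponential censoring
#'   process (per month).
#' @param seed integer master seed.
#' @return An object of class `gx_ground_truth`.
#' @export
ground_truth <- function(beta_surv = NULL, beta_marker = NULL,
                         baseline_hazard_rate = log(2) / 12,
                         censor_rate = 0.015, seed = 1L) {
  if (baseline_hazard_rate <= 0 || censor_rate <= 0)
    stop("hazard and censoring rates must be strictly positive", call. = FALSE)
  if (is.null(beta_surv)) {
    beta_surv <- c(log_tumor_volume = 0.40, multifocality = 0.55,
                   subependymal_extension = 0.55, edema_high = -0.60,
                   adjuvant_non_stupp = 1.20, age_over_70 = 0.30)
  }
  if (is.null(beta_marker)) {
    beta_marker <- list(
      MGMT = c("(Intercept)" = -1.0, edema_fraction = 0.8),
      EGFR = c("(Intercept)" = -0.5, log_tumor_volume = 0.7,
               necrosis_fraction = 0.8),
      IDH1 = c("(Intercept)" = -2.4, log_tumor_volume = -0.8))
  }
  structure(list(beta_surv = beta_surv, beta_marker = beta_marker,
                 baseline_hazard_rate = baseline_hazard_rate,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "gx_ground_truth")
}

# Smooth multiplicative bias field: product of per-axis quadratics with
# random coefficients, normalised to mean 1 -- low-frequency by construction.
make_bias_field <- function(dims, amplitude) {
  if (amplitude == 0) return(array(1, dims))
  axis_poly <- function(n) {
    u <- if (n > 1) seq(-1, 1, length.out = n) else 0
    c1 <- runif(1, -1, 1) * amplitude / 2
    c2 <- runif(1, -1, 1) * amplitude / 2
    1 + c1 * u + c2 * (u^2 - 1 / 3)
  }
  qx <- axis_poly(dims[1]); qy <- axis_poly(dims[2]); qz <- axis_poly(dims[3])
  field <- outer(outer(qx, qy), qz)
  field <- field / mean(field)
  pmax(field, 1e-3)
}

# Binary ellipsoid on voxel-center coordinates (mm).
ellipsoid_mask <- function(dims, spacing, center_mm, semi_axes_mm) {
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dims[3]) - 0.5) * spacing[3]
  dx2 <- ((cx - center_mm[1]) / semi_axes_mm[1])^2
  dy2 <- ((cy - center_mm[2]) / semi_axes_mm[2])^2
  dz2 <- ((cz - center_mm[3]) / semi_axes_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Generate one synthetic co-registered T1+Gd / T2 tumor phantom
#'
#' Builds piecewise-constant tissue phantoms on the scanner's voxel grid: a
#' bright enhancing rim with a dark necrotic core on T1+Gd, and a bright
#' tumor-plus-edema region on T2. The clean phantom is multiplied by a smooth
#' random bias field and corrupted with i.i.d. Gaussian noise according to the
#' scanner profile. T1 and T2 are generated on the same grid (co-registered),
#' so the T2 tumor/edema mask contains the T1 enhancing mask by construction.
#'
#' @param profile a [scanner_profile()].
#' @param shape_params list with elements `fov_mm` (length-3 field of view),
#'   `center_mm` (tumor centre; default FOV centre), `semi_axes_mm` (length-3
#'   enhancing-tumor semi-axes), `core_frac` (necrotic-core semi-axis
#'   fraction), `edema_scale` (edema semi-axis multiplier, >= 1), and
#'   optionally `second_lesion` (list with `center_mm`, `semi_axes_mm`).
#' @param seed integer seed; the same seed reproduces the volumes bit for bit.
#' @return List with `t1`, `t2` ([gx_image]s), logical arrays `t1_mask`,
#'   `t2_mask`, and the `levels` used per modality.
#' @export
generate_tumor_volume <- function(profile, shape_params = list(), seed = 1L) {
  sp <- c(profile$pixel_spacing_mm, profile$slice_thickness_mm)
  p <- modifyList(list(fov_mm = c(64, 64, 44), center_mm = NULL,
                       semi_axes_mm = c(14, 11, 9), core_frac = 0.5,
                       edema_scale = 1.5, second_lesion = NULL), shape_params)
  if (is.null(p$center_mm)) p$center_mm <- p$fov_mm / 2
  halo <- p$semi_axes_mm * p$edema_scale
  if (any(p$center_mm - halo < 0) || any(p$center_mm + halo > p$fov_mm))
    stop("tumor (including edema halo) exceeds the field of view", call. = FALSE)
  if (!is.null(p$second_lesion)) {
    s <- p$second_lesion
    if (any(s$center_mm - s$semi_axes_mm * p$edema_scale < 0) ||
        any(s$center_mm + s$semi_axes_mm * p$edema_scale > p$fov_mm))
      stop("second lesion exceeds the field of view", call. = FALSE)
  }
  dims <- pmax(2L, as.integer(round(p$fov_mm / sp)))
  with_seed(seed, {
    tumor <- ellipsoid_mask(dims, sp, p$center_mm, p$semi_axes_mm)
    core <- ellipsoid_mask(dims, sp, p$center_mm, p$semi_axes_mm * p$core_frac)
    edema <- ellipsoid_mask(dims, sp, p$center_mm, halo)
    if (!is.null(p$second_lesion)) {
      s <- p$second_lesion
      t2nd <- ellipsoid_mask(dims, sp, s$center_mm, s$semi_axes_mm)
      c2nd <- ellipsoid_mask(dims, sp, s$center_mm, s$semi_axes_mm * p$core_frac)
      e2nd <- ellipsoid_mask(dims, sp, s$center_mm, s$semi_axes_mm * p$edema_scale)
      tumor <- tumor | t2nd; core <- core | c2nd; edema <- edema | e2nd
    }
    core <- core & tumor
    edema <- edema | tumor
    lev_t1 <- c(background = 0.30, rim = 1.00, core = 0.15)
    lev_t2 <- c(background = 0.25, tumor = 0.55, edema = 0.85)
    t1v <- array(lev_t1["background"], dims)
    t1v[tumor] <- lev_t1["rim"]; t1v[core] <- lev_t1["core"]
    t2v <- array(lev_t2["background"], dims)
    t2v[edema] <- lev_t2["edema"]; t2v[tumor] <- lev_t2["tumor"]
    for (nm in c("t1v", "t2v")) {
      v <- get(nm)
      v <- v * make_bias_field(dims, profile$bias_amplitude)
      if (profile$noise_sd > 0)
        v <- v + array(rnorm(prod(dims), 0, profile$noise_sd), dims)
      assign(nm, v)
    }
    list(t1 = gx_image(t1v, sp, "T1Gd"), t2 = gx_image(t2v, sp, "T2"),
         t1_mask = tumor, t2_mask = edema,
         levels = list(T1Gd = lev_t1, T2 = lev_t2))
  })
}

#' Simulate survival outcomes from a log-linear hazard
#'
#' Event times are exponential with rate
#' `baseline_hazard_rate * exp(sum(beta * x))`; censoring times are
#' independent exponential with rate `censor_rate`. The observed time is the
#' minimum, the event indicator is 1 when death precedes censoring.
#'
#' @param features data frame or matrix of per-patient features containing
#'   every feature named in `gt$beta_surv`.
#' @param gt a [ground_truth()].
#' @param seed integer seed.
#' @return Data frame with columns `time` (months) and `event` (0/1).
#' @export
simulate_survival <- function(features, gt, seed = gt$seed) {
  features <- as.data.frame(features)
  need <- names(gt$beta_surv)
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("features missing for survival simulation: ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- as.matrix(features[, need, drop = FALSE])
  lp <- drop(x %*% gt$beta_surv)
  n <- nrow(x)
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = gt$baseline_hazard_rate * exp(lp))
    t_cens <- stats::rexp(n, rate = gt$censor_rate)
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  })
}

# Raw (pre-recoding) edema category from the latent edema volume fraction.
edema_raw_category <- function(frac) {
  cut(frac, breaks = c(-Inf, 0.05, 0.45, 0.70, Inf),
      labels = c("none", "less_than_third", "third_to_two_thirds",
                 "over_two_thirds"))
}

# Draw one synthetic patient: geometry, images (optional), latent features,
# VASARI raw codes, clinical record, markers and survival inputs.
draw_patient <- function(profile, gt, seed, images = TRUE,
                         image_params = list()) {
  with_seed(seed, {
    fov <- if (!is.null(image_params$fov_mm)) image_params$fov_mm else c(64, 64, 44)
    axes <- exp(rnorm(3, log(c(13, 11, 9)), 0.18))
    axes <- pmin(axes, fov / 4)
    edema_scale <- runif(1, 1.15, 1.75)
    core_frac <- runif(1, 0.3, 0.7)
    center <- fov / 2 + runif(3, -0.05, 0.05) * fov
    multifocal <- runif(1) < 0.2
    second <- NULL
    if (multifocal) {
      a2 <- axes * runif(1, 0.3, 0.5)
      off <- sign(fov / 2 - center) * (axes * edema_scale + a2 * edema_scale + 2)
      c2 <- center + off * c(1, 0.4, 0.3)
      c2 <- pmin(pmax(c2, a2 * edema_scale + 0.5), fov - a2 * edema_scale - 0.5)
      second <- list(center_mm = c2, semi_axes_mm = a2)
    }
    shape <- modifyList(list(fov_mm = fov, center_mm = center,
                             semi_axes_mm = axes, core_frac = core_frac,
                             edema_scale = edema_scale, second_lesion = second),
                        image_params[setdiff(names(image_params), "fov_mm")])
    img_seed <- derive_seed(seed, 11L)

    # latent geometry-derived quantities (ground truth for features/VASARI)
    vol_t1 <- 4 / 3 * pi * prod(axes) * (1 + if (multifocal)
      prod(second$semi_axes_mm) / prod(axes) else 0)
    vol_t2 <- vol_t1 * edema_scale^3
    edema_fraction <- 1 - vol_t1 / vol_t2
    necrosis_fraction <- core_frac^3
    log_tumor_volume <- (log(vol_t1) - log(4 / 3 * pi * 13 * 11 * 9)) / 0.6

    age <- min(max(rnorm(1, 61, 12), 18), 85)
    sex <- sample(c("male", "female"), 1, prob = c(0.6, 0.4))
    surgery <- sample(c("biopsy", "resection"), 1, prob = c(0.38, 0.62))
    adjuvant <- sample(c("STUPP", "non-STUPP"), 1, prob = c(0.47, 0.53))

    subependymal <- runif(1) < stats::plogis(-0.6 + 0.9 * log_tumor_volume)
    eloquent <- runif(1) < stats::plogis(-0.8 + 2 * (center[1] / fov[1] - 0.5))
    t1flair <- runif(1) < 0.3
    latent <- data.frame(
      log_tumor_volume = log_tumor_volume,
      multifocality = as.integer(multifocal),
      subependymal_extension = as.integer(subependymal),
      edema_fraction = edema_fraction,
      edema_high = as.integer(edema_fraction > 0.70),
      necrosis_fraction = necrosis_fraction,
      adjuvant_non_stupp = as.integer(adjuvant == "non-STUPP"),
      age_over_70 = as.integer(age > 70),
      eloquent_cortex = as.integer(eloquent),
      t1flair_increased = as.integer(t1flair))

    vasari_raw <- data.frame(
      eloquent_cortex = ifelse(eloquent, "yes", "no"),
      multifocality = ifelse(multifocal, "yes", "no"),
      subependymal_extension = ifelse(subependymal, "yes", "no"),
      edema_proportion = as.character(edema_raw_category(edema_fraction)),
      t1_flair_ratio = ifelse(t1flair, "increased", "not_increased"),
      major_axis_mm = 2 * max(axes),
      minor_axis_mm = 2 * min(axes),
      location = sample(c("frontal", "temporal", "parietal", "occipital"), 1),
      tumor_side = sample(c("left", "right"), 1),
      proportion_necrosis = as.character(cut(necrosis_fraction,
        c(-Inf, 0.05, 1 / 3, 2 / 3, Inf),
        labels = c("none", "less_than_third", "third_to_two_thirds",
                   "over_two_thirds"))),
      proportion_nonenhancing = sample(c("none", "less_than_third",
        "third_to_two_thirds"), 1, prob = c(0.5, 0.35, 0.15)),
      thickness_enhancing_margin = sample(c("thin", "thick"), 1,
                                          prob = c(0.45, 0.55)),
      definition_enhancing_margin = sample(c("well_defined", "poorly_defined"),
                                           1, prob = c(0.6, 0.4)),
      hemorrhage = ifelse(runif(1) < 0.25, "yes", "no"),
      pial_invasion = ifelse(runif(1) < 0.3, "yes", "no"),
      deep_wm_invasion = ifelse(runif(1) <
        stats::plogis(-1 + 0.8 * log_tumor_volume), "yes", "no"),
      midline_cross = ifelse(runif(1) <
        stats::plogis(-1.5 + 1.0 * log_tumor_volume), "yes", "no"))

    clinical <- data.frame(age = age, sex = sex, surgery = surgery,
                           adjuvant = adjuvant)

    marker_draw <- function(beta) {
      eta <- unname(beta["(Intercept)"])
      if (is.na(eta)) eta <- 0
      for (nm in setdiff(names(beta), "(Intercept)"))
        eta <- eta + beta[[nm]] * latent[[nm]]
      as.integer(runif(1) < stats::plogis(eta))
    }
    markers <- data.frame(MGMT = marker_draw(gt$beta_marker$MGMT),
                          EGFR = marker_draw(gt$beta_marker$EGFR),
                          IDH1 = marker_draw(gt$beta_marker$IDH1))

    vols <- if (images) generate_tumor_volume(profile, shape, img_seed) else NULL
    list(latent = latent, vasari_raw = vasari_raw, clinical = clinical,
         markers = markers, volumes = vols, shape = shape,
         spacing = c(profile$pixel_spacing_mm, profile$slice_thickness_mm))
  })
}

#' Generate paired training and validation cohorts with known ground truth
#'
#' Draws two cohorts from different scanner-profile mixtures (emulating two
#' independent multi-centre datasets), each patient with co-registered T1+Gd /
#' T2 phantoms and masks, a raw VASARI table, a clinical table, molecular
#' markers (with optional missingness) and survival generated from the ground
#' truth's log-linear hazard over latent features. Everything is a
#' deterministic function of `gt$seed`.
#'
#' @param n_train,n_val cohort sizes (>= 1). Defaults match the study-scale
#'   cohort sizes of 142 and 46.
#' @param profiles list with elements `train` and `val`, each a list of
#'   [scanner_profile()]s sampled uniformly per patient.
#' @param gt a [ground_truth()].
#' @param images generate image volumes (set `FALSE` for tabular-only
#'   simulation studies).
#' @param image_params list forwarded to the phantom generator (`fov_mm`, ...).
#' @param missing_marker_frac fraction of marker values set missing at random.
#' @param out_dir optional directory; when given, images/masks are written as
#'   NIfTI, tables as CSV and the ground truth as JSON.
#' @return List with `train`, `val` (each: `patients`, `clinical`, `vasari`,
#'   `survival`, `markers`, `latent`, `spacings`) and `ground_truth`.
#' @export
generate_cohorts <- function(n_train = 142L, n_val = 46L, profiles = NULL,
                             gt = ground_truth(), images = TRUE,
                             image_params = list(),
                             missing_marker_frac = 0.05, out_dir = NULL) {
  if (n_train < 1 || n_val < 1) stop("cohort sizes must be >= 1", call. = FALSE)
  if (is.null(profiles)) {
    profiles <- list(
      train = list(scanner_profile(c(0.9, 0.9), 5.0, 0.15, 0.02),
                   scanner_profile(c(1.0, 1.0), 5.5, 0.25, 0.03),
                   scanner_profile(c(0.8, 0.8), 6.0, 0.20, 0.02)),
      val = list(scanner_profile(c(1.1, 1.1), 6.0, 0.30, 0.04),
                 scanner_profile(c(0.7, 0.7), 5.0, 0.20, 0.02)))
  }
  build <- function(n, profs, tag, stream) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      seed_i <- derive_seed(gt$seed, stream * 100000L + i)
      prof <- profs[[with_seed(seed_i, sample.int(length(profs), 1L))]]
      rows[[i]] <- draw_patient(prof, gt, derive_seed(seed_i, 7L),
                                images = images, image_params = image_params)
    }
    ids <- sprintf("%s_%03d", tag, seq_len(n))
    bind <- function(getter) {
      out <- do.call(rbind, lapply(rows, getter))
      cbind(data.frame(patient_id = ids), out)
    }
    latent <- bind(function(r) r$latent)
    surv <- simulate_survival(latent, gt, seed = derive_seed(gt$seed,
                                                             stream + 55L))
    surv <- cbind(data.frame(patient_id = ids), surv)
    markers <- bind(function(r) r$markers)
    if (missing_marker_frac > 0) {
      markers[-1] <- lapply(markers[-1], function(col) {
        drop_idx <- with_seed(derive_seed(gt$seed, stream + 77L),
                              runif(n) < missing_marker_frac)
        col[drop_idx] <- NA_integer_
        col
      })
    }
    list(patients = rows, ids = ids,
         clinical = bind(function(r) r$clinical),
         vasari = bind(function(r) r$vasari_raw),
         latent = latent, survival = surv, markers = markers,
         spacings = bind(function(r)
           data.frame(dx = r$spacing[1], dy = r$spacing[2], dz = r$spacing[3])))
  }
  train <- build(n_train, profiles$train, "train", 1L)
  val <- build(n_val, profiles$val, "val", 2L)
  out <- list(train = train, val = val, ground_truth = gt)
  if (!is.null(out_dir)) write_cohorts(out, out_dir, images = images)
  out
}

# Serialise a generated cohort pair: NIfTI volumes/masks, CSV tables, JSON gt.
write_cohorts <- function(cohorts, out_dir, images = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tag in c("train", "val")) {
    co <- cohorts[[tag]]
    d <- file.path(out_dir, tag)
    dir.create(d, showWarnings = FALSE)
    for (nm in c("clinical", "vasari", "survival", "markers", "spacings"))
      utils::write.csv(co[[nm]], file.path(d, paste0(nm, ".csv")),
                       row.names = FALSE)
    if (images) {
      for (i in seq_along(co$patients)) {
        v <- co$patients[[i]]$volumes
        if (is.null(v)) next
        id <- co$ids[i]
        write_nifti_volume(v$t1, file.path(d, paste0(id, "_t1.nii.gz")))
        write_nifti_volume(v$t2, file.path(d, paste0(id, "_t2.nii.gz")))
        write_nifti_volume(gx_image(array(as.numeric(v$t1_mask), dim(v$t1_mask)),
                                    v$t1$spacing, "mask"),
                           file.path(d, paste0(id, "_t1_mask.nii.gz")))
        write_nifti_volume(gx_image(array(as.numeric(v$t2_mask), dim(v$t2_mask)),
                                    v$t2$spacing, "mask"),
                           file.path(d, paste0(id, "_t2_mask.nii.gz")))
      }
    }
  }
  gt <- cohorts$ground_truth
  write_json_file(list(beta_surv = as.list(gt$beta_surv),
                       beta_marker = lapply(gt$beta_marker, as.list),
                       baseline_hazard_rate = gt$baseline_hazard_rate,
                       censor_rate = gt$censor_rate, seed = gt$seed),
                  file.path(out_dir, "ground_truth.json"))
  invisible(out_dir)
}
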