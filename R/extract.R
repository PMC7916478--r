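#' Filter-bank and feature-inventory configuration
#'
#' Controls which derived images and feature classes the extractor computes.
#' Defaults: LoG at physical scales 2, 3, 4, 5 mm, a single-level undecimated
#' Coiflet-1 wavelet decomposition (8 sub-bands), all five texture classes
#' plus first-order on every derived image, and shape on the original mask
#' geometry. Discretization uses a fixed bin count (32 by default): inputs
#' are Z-scored, so a fixed bin *width* would be unit-dependent.
#'
#' @param log_sigmas_mm positive LoG scales in mm.
#' @param wavelet logical, include the 8 wavelet sub-bands.
#' @param n_bins gray levels for discretization.
#' @param classes texture/first-order classes to compute per derived image.
#' @param shape logical, include shape features (original mask only).
#' @return A list of class `gx_filter_bank_config`.
#' @export
filter_bank_config <- function(log_sigmas_mm = c(2, 3, 4, 5), wavelet = TRUE,
                               n_bins = 32L,
                               classes = c("firstorder", "glcm", "glrlm",
                                           "glszm", "gldm", "ngtdm"),
                               shape = TRUE) {
  if (any(log_sigmas_mm <= 0)) stop("LoG sigmas must be positive", call. = FALSE)
  structure(list(log_sigmas_mm = log_sigmas_mm, wavelet = wavelet,
                 n_bins = as.integer(n_bins), classes = classes,
                 shape = shape),
            class = "gx_filter_bank_config")
}

# Derived images for one modality: named list filter-label -> gx_image.
derived_images <- function(img, config) {
  out <- list(original = img)
  for (s in config$log_sigmas_mm)
    out[[sprintf("log.sigma.%.1f.mm.3D", s)]] <-
      suppressWarnings(log_filter(img, s))
  if (isTRUE(config$wavelet)) {
    wb <- wavelet_decompose(img)
    for (lab in names(wb)) out[[paste0("wavelet.", lab)]] <- wb[[lab]]
  }
  out
}

# Feature classes for one derived image over one mask.
image_class_features <- function(img, mask, config) {
  out <- c()
  if ("firstorder" %in% config$classes) {
    fo <- first_order_features(img, mask, config$n_bins)
    out <- c(out, stats::setNames(fo, paste0("firstorder_", names(fo))))
  }
  tex <- intersect(config$classes, c("glcm", "glrlm", "glszm", "gldm", "ngtdm"))
  if (length(tex)) {
    dimg <- discretize(img, mask, config$n_bins)
    mats <- texture_matrices(dimg)
    all_tex <- texture_features(mats)
    keep <- sub("_.*", "", names(all_tex)) %in% tex
    out <- c(out, all_tex[keep])
  }
  out
}

#' Extract the full radiomics feature vector for one patient
#'
#' For each modality (T1+Gd, T2): first-order and texture classes on the
#' original image and on every LoG- and wavelet-derived image, plus shape
#' features on the original (unfiltered) mask geometry. Feature ids follow
#' the `{modality}_{filter}_{class}_{name}` grammar (e.g.
#' `T2_log.sigma.3.0.mm.3D_glszm_LargeAreaLowGrayLevelEmphasis`). Features
#' that are undefined on the region (e.g. Correlation on a single-level
#' region) are kept as `NA` and recorded in the manifest with a reason,
#' never silently dropped.
#'
#' @param t1,t2 preprocessed [gx_image]s.
#' @param masks list with logical arrays `T1Gd` and `T2` on the corresponding
#'   image grids.
#' @param config a [filter_bank_config()].
#' @return Named numeric feature vector with attribute `"manifest"` (data
#'   frame: id, modality, filter, class, name, defined, reason).
#' @export
extract_features <- function(t1, t2, masks, config = filter_bank_config()) {
  mods <- list(T1 = list(img = t1, mask = masks$T1Gd),
               T2 = list(img = t2, mask = masks$T2))
  feats <- c()
  for (mod in names(mods)) {
    img <- mods[[mod]]$img
    mask <- mods[[mod]]$mask
    if (isTRUE(config$shape)) {
      sf <- shape_features(mask, img$spacing)
      feats <- c(feats, stats::setNames(sf,
        paste0(mod, "_original_shape_", names(sf))))
    }
    dimgs <- derived_images(img, config)
    for (filt in names(dimgs)) {
      fv <- image_class_features(dimgs[[filt]], mask, config)
      feats <- c(feats, stats::setNames(fv, paste0(mod, "_", filt, "_",
                                                   names(fv))))
    }
  }
  parts <- strsplit(names(feats), "_")
  manifest <- data.frame(
    id = names(feats),
    modality = vapply(parts, `[`, "", 1L),
    filter = vapply(parts, `[`, "", 2L),
    class = vapply(parts, `[`, "", 3L),
    name = vapply(parts, function(p) paste(p[-(1:3)], collapse = "_"), ""),
    defined = is.finite(feats),
    reason = ifelse(is.finite(feats), "", "undefined on region"))
  attr(feats, "manifest") <- manifest
  feats
}

#' Number of features the current configuration yields per patient
#'
#' Computed on a tiny probe phantom; the inventory is configuration-driven
#' and stable across runs.
#'
#' @param config a [filter_bank_config()].
#' @return Integer feature count.
#' @export
feature_inventory_size <- function(config = filter_bank_config()) {
  arr <- array(seq_len(6 * 6 * 3) %% 7 + sin(seq_len(108)), c(6, 6, 3))
  img <- gx_image(arr, c(1, 1, 1))
  mask <- array(TRUE, c(6, 6, 3))
  length(extract_features(img, gx_image(arr, c(1, 1, 1), "T2"),
                          list(T1Gd = mask, T2 = mask), config))
}
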