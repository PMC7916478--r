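# Keys cubic-convolution kernel (a = -0.5): interpolates, reproduces affine
# functions exactly, support of 4 samples.
keys_kernel <- function(t) {
  a <- -0.5
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

linear_kernel <- function(t) pmax(0, 1 - abs(t))

# Row-stochastic 1D resampling operator from n_in samples at spacing d_in to
# n_out samples at spacing d_out, voxel-center aligned, edge-replicated.
resample_weights <- function(n_in, d_in, n_out, d_out, kernel, support) {
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    s <- ((i - 0.5) * d_out) / d_in - 0.5      # 0-based source coordinate
    j <- floor(s) + seq(-support + 1L, support)
    w <- kernel(s - j)
    j <- pmin(pmax(j, 0), n_in - 1)            # replicate edges
    for (k in seq_along(j)) W[i, j[k] + 1] <- W[i, j[k] + 1] + w[k]
  }
  W / rowSums(W)
}

#' Resample a volume to a target voxel spacing
#'
#' In-plane interpolation is bicubic (cubic convolution over a 4x4 sample
#' neighbourhood); through-plane interpolation is linear, a deliberately
#' conservative choice given thick slices. The output grid spans the same
#' physical extent as the input (voxel-center aligned); a single-slice input
#' is passed through unchanged along the slice axis.
#'
#' @param img a [gx_image].
#' @param target_spacing length-3 positive spacing in mm; the default is the
#'   fixed reference geometry of 0.449 mm in-plane and 5.5 mm through-plane.
#' @return A resampled [gx_image].
#' @export
resample_volume <- function(img, target_spacing = c(0.449, 0.449, 5.5)) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 2L)
    target_spacing <- c(target_spacing, img$spacing[3])
  if (any(target_spacing <= 0)) stop("target spacing must be positive", call. = FALSE)
  d <- dim(img$values)
  n_out <- pmax(1L, as.integer(round(d * img$spacing / target_spacing)))
  if (d[3] == 1L) { n_out[3] <- 1L; target_spacing[3] <- img$spacing[3] }
  v <- img$values
  if (!(n_out[1] == d[1] && target_spacing[1] == img$spacing[1])) {
    W <- resample_weights(d[1], img$spacing[1], n_out[1], target_spacing[1],
                          keys_kernel, 2L)
    v <- array(W %*% matrix(v, d[1]), c(n_out[1], d[2], d[3]))
    d <- dim(v)
  }
  if (!(n_out[2] == d[2] && target_spacing[2] == img$spacing[2])) {
    W <- resample_weights(d[2], img$spacing[2], n_out[2], target_spacing[2],
                          keys_kernel, 2L)
    v <- aperm(array(W %*% matrix(aperm(v, c(2, 1, 3)), d[2]),
                     c(n_out[2], d[1], d[3])), c(2, 1, 3))
    d <- dim(v)
  }
  if (!(n_out[3] == d[3] && target_spacing[3] == img$spacing[3])) {
    W <- resample_weights(d[3], img$spacing[3], n_out[3], target_spacing[3],
                          linear_kernel, 1L)
    v <- aperm(array(W %*% matrix(aperm(v, c(3, 1, 2)), d[3]),
                     c(n_out[3], d[1], d[2])), c(2, 3, 1))
  }
  gx_image(v, target_spacing, img$modality)
}

#' Correct a smooth multiplicative intensity bias field
#'
#' Estimates the low-frequency multiplicative bias that is intrinsic to MR
#' acquisitions by robust regression in the log-intensity domain: an additive
#' per-axis polynomial field (smooth and low-frequency by construction) is fit
#' with iteratively reweighted least squares, down-weighting anatomy-driven
#' outliers so the field tracks the acquisition bias rather than tissue
#' contrast. The image is divided by the exponentiated zero-mean field, so the
#' global intensity scale is preserved. Non-positive inputs are shifted before
#' the log transform and shifted back afterwards; the shift is recorded.
#'
#' @param img a [gx_image].
#' @param mask optional logical array restricting field *estimation* (the
#'   correction is always applied to the whole volume). Default: whole volume.
#' @param degree per-axis polynomial degree of the field model.
#' @param iterations IRLS iterations (Tukey bisquare weights).
#' @return A corrected [gx_image]. Attributes: `bias_field` (the estimated
#'   multiplicative field), `shift` (intensity shift applied), and
#'   `converged` (`FALSE` with a warning if the fit degenerated, in which case
#'   the input is returned unchanged).
#' @export
correct_bias_field <- function(img, mask = NULL, degree = 4L, iterations = 3L) {
  d <- dim(img$values)
  if (!is.null(mask)) {
    if (!any(mask)) stop("bias-field mask is empty", call. = FALSE)
  }
  v <- img$values
  shift <- 0
  mn <- min(v)
  if (mn <= 0) shift <- -mn + 1e-3 * max(diff(range(v)), 1e-6)
  lv <- log(v + shift)
  basis_axis <- function(n) stats::poly(seq_len(n), degree = min(degree, n - 1L))
  bx <- basis_axis(d[1]); by <- basis_axis(d[2])
  bz <- if (d[3] > 1) basis_axis(d[3]) else NULL
  idx <- arrayInd(seq_along(lv), d)
  X <- cbind(1, bx[idx[, 1], , drop = FALSE], by[idx[, 2], , drop = FALSE],
             if (!is.null(bz)) bz[idx[, 3], , drop = FALSE])
  fit_rows <- if (is.null(mask)) seq_len(nrow(X)) else which(as.logical(mask))
  y <- as.vector(lv)[fit_rows]
  Xf <- X[fit_rows, , drop = FALSE]
  w <- rep(1, length(y))
  coefs <- NULL
  for (it in seq_len(iterations)) {
    f <- tryCatch(stats::lm.wfit(Xf, y, w), error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f$coefficients[!is.na(f$coefficients)]))) {
      warning("bias-field fit did not converge; returning input unchanged")
      out <- img
      attr(out, "converged") <- FALSE
      return(out)
    }
    coefs <- ifelse(is.na(f$coefficients), 0, f$coefficients)
    r <- y - drop(Xf %*% coefs)
    s <- stats::mad(r)
    if (s < 1e-12) break
    u <- r / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) < ncol(Xf)) w <- rep(1, length(y))
  }
  field_log <- drop(X %*% coefs)
  field_log <- field_log - mean(field_log)
  field <- array(exp(field_log), d)
  out <- gx_image((v + shift) / field - shift, img$spacing, img$modality)
  attr(out, "bias_field") <- field
  attr(out, "shift") <- shift
  attr(out, "converged") <- TRUE
  out
}

#' Global histogram equalization
#'
#' Maps every voxel through the empirical CDF of the volume's own intensities,
#' yielding values in (0, 1] with preserved rank order (a strictly monotone
#' transform of the input gives an identical output).
#'
#' @param img a [gx_image].
#' @return An equalized [gx_image].
#' @export
equalize_histogram <- function(img) {
  v <- img$values
  n <- length(v)
  out <- array(rank(v, ties.method = "max") / n, dim(v))
  gx_image(out, img$spacing, img$modality)
}

#' Z-score normalization parameters
#'
#' @param mu mean. @param sigma positive standard deviation.
#' @param modality modality tag the parameters belong to.
#' @return An object of class `gx_zscore_params`.
#' @export
zscore_params <- function(mu, sigma, modality = "T1Gd") {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be strictly positive", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, modality = modality),
            class = "gx_zscore_params")
}

#' Estimate Z-score parameters on a training cohort
#'
#' Pools all voxel intensities of the supplied (already resampled /
#' bias-corrected / equalized) training images of one modality and returns
#' their mean and population standard deviation. These parameters are frozen
#' and *transferred* to any validation cohort: validation images are
#' normalized with the training `mu`/`sigma`, never re-estimated.
#'
#' @param imgs list of [gx_image]s (>= 1) of a single modality.
#' @return A [zscore_params()] object.
#' @export
estimate_zscore_params <- function(imgs) {
  if (inherits(imgs, "gx_image")) imgs <- list(imgs)
  if (!length(imgs)) stop("need at least one training image", call. = FALSE)
  pooled <- unlist(lapply(imgs, function(i) as.vector(i$values)))
  mu <- mean(pooled)
  sigma <- sqrt(mean((pooled - mu)^2))
  if (sigma <= 0) stop("pooled intensity variance is zero", call. = FALSE)
  zscore_params(mu, sigma, imgs[[1]]$modality)
}

#' @rdname estimate_zscore_params
#' @param img a [gx_image]. @param params a [zscore_params()].
#' @export
apply_zscore <- function(img, params) {
  gx_image((img$values - params$mu) / params$sigma, img$spacing, img$modality)
}

#' Preprocessing configuration
#'
#' @param target_spacing length-3 spacing in mm, or `NULL` to use the mode of
#'   the training cohort's spacing distribution (computed per axis).
#' @param resample,bias_correct,equalize step toggles.
#' @param zscore named list of [zscore_params()] per modality, or `NULL` to
#'   skip the Z-score step (e.g. while estimating the parameters themselves).
#'   The frozen study values (T1 mu 0.1904 / sigma 0.2313, T2 mu 0.2009 /
#'   sigma 0.2448) can be supplied here to reproduce a fixed transform.
#' @param bias_degree,bias_iterations bias-field model settings.
#' @return A list of class `gx_preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = c(0.449, 0.449, 5.5),
                              resample = TRUE, bias_correct = TRUE,
                              equalize = TRUE, zscore = NULL,
                              bias_degree = 4L, bias_iterations = 3L) {
  structure(list(target_spacing = target_spacing, resample = resample,
                 bias_correct = bias_correct, equalize = equalize,
                 zscore = zscore, bias_degree = bias_degree,
                 bias_iterations = bias_iterations),
            class = "gx_preprocess_config")
}

#' Per-axis mode of a cohort's voxel-spacing distribution
#'
#' @param spacings data frame with columns `dx`, `dy`, `dz` (mm).
#' @return Length-3 numeric target spacing.
#' @export
spacing_mode <- function(spacings) {
  one <- function(x) {
    tab <- table(round(x, 6))
    as.numeric(names(tab)[which.max(tab)])
  }
  c(one(spacings$dx), one(spacings$dy), one(spacings$dz))
}

#' Run the full preprocessing chain on one image
#'
#' Applies, in order: geometric resampling, bias-field correction, global
#' histogram equalization, and the frozen Z-score transform for the image's
#' modality. Each applied step is appended to a provenance log stored in the
#' `"log"` attribute. The chain is deterministic.
#'
#' @param img a [gx_image].
#' @param config a [preprocess_config()].
#' @return The preprocessed [gx_image] with a `"log"` attribute.
#' @export
preprocess_pipeline <- function(img, config = preprocess_config()) {
  log <- list()
  if (isTRUE(config$resample) && !is.null(config$target_spacing)) {
    img2 <- resample_volume(img, config$target_spacing)
    log$resample <- list(from = img$spacing, to = img2$spacing,
                         dims = dim(img2$values))
    img <- img2
  }
  if (isTRUE(config$bias_correct)) {
    img2 <- correct_bias_field(img, degree = config$bias_degree,
                               iterations = config$bias_iterations)
    log$bias_correct <- list(converged = isTRUE(attr(img2, "converged")),
                             shift = attr(img2, "shift"))
    img <- gx_image(img2$values, img2$spacing, img2$modality)
  }
  if (isTRUE(config$equalize)) {
    img <- equalize_histogram(img)
    log$equalize <- TRUE
  }
  if (!is.null(config$zscore)) {
    zp <- config$zscore[[img$modality]]
    if (is.null(zp)) stop("no Z-score parameters for modality ", img$modality,
                          call. = FALSE)
    img <- apply_zscore(img, zp)
    log$zscore <- list(mu = zp$mu, sigma = zp$sigma)
  }
  attr(img, "log") <- log
  img
}
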