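# 1D correlation along one axis of a 3D array with mirror (reflect) padding.
# taps: numeric kernel; offsets: integer sample offsets relative to the output
# position (same length as taps).
filter_axis <- function(v, taps, offsets, axis) {
  d <- dim(v)
  n <- d[axis]
  idx_clamp <- function(i) {
    # reflect about the edges (..., 2, 1 | 1, 2, ...)
    i <- ifelse(i < 1L, 2L - i, i)
    i <- ifelse(i > n, 2L * n + 1L - i, i)
    pmin(pmax(i, 1L), n)
  }
  W <- matrix(0, n, n)
  for (k in seq_along(taps)) {
    j <- idx_clamp(seq_len(n) + offsets[k])
    W[cbind(seq_len(n), j)] <- W[cbind(seq_len(n), j)] + taps[k]
  }
  if (axis == 1L) {
    array(W %*% matrix(v, d[1]), d)
  } else if (axis == 2L) {
    aperm(array(W %*% matrix(aperm(v, c(2, 1, 3)), d[2]), d[c(2, 1, 3)]),
          c(2, 1, 3))
  } else {
    aperm(array(W %*% matrix(aperm(v, c(3, 1, 2)), d[3]), d[c(3, 1, 2)]),
          c(2, 3, 1))
  }
}

gaussian_taps <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- seq(-r, r)
  w <- exp(-x^2 / (2 * sigma_vox^2))
  list(taps = w / sum(w), offsets = x)
}

#' Laplacian-of-Gaussian filter at a physical scale
#'
#' Smooths with a separable Gaussian whose physical width is `sigma_mm`
#' (converted to voxels per axis via the image spacing), applies the discrete
#' Laplacian (second central differences scaled by the squared spacing), and
#' multiplies by `sigma_mm^2` (scale normalisation), so responses are
#' comparable across scales and blob-like structure of radius ~ `sigma_mm` is
#' emphasised. The operator is linear and annihilates constants and affine
#' ramps (up to boundary effects).
#'
#' @param img a [gx_image].
#' @param sigma_mm positive filter scale in mm. A value below half the largest
#'   voxel dimension is under-resolved and triggers a warning.
#' @return A filtered [gx_image].
#' @export
log_filter <- function(img, sigma_mm) {
  if (sigma_mm <= 0) stop("sigma must be positive", call. = FALSE)
  if (sigma_mm < max(img$spacing) / 2)
    warning("LoG sigma ", sigma_mm, " mm is under-resolved for voxel spacing ",
            paste(signif(img$spacing, 3), collapse = "x"), " mm")
  v <- img$values
  d <- dim(v)
  for (a in 1:3) {
    if (d[a] < 2) next
    g <- gaussian_taps(max(sigma_mm / img$spacing[a], 0.3))
    v <- filter_axis(v, g$taps, g$offsets, a)
  }
  lap <- array(0, d)
  for (a in 1:3) {
    if (d[a] < 3) next
    second <- filter_axis(v, c(1, -2, 1) / img$spacing[a]^2, c(-1L, 0L, 1L), a)
    lap <- lap + second
  }
  gx_image(sigma_mm^2 * lap, img$spacing, img$modality)
}

# Coiflet-1 analysis filters, normalised to unit DC gain (low-pass sums to 1,
# high-pass to 0) so sub-bands live on the intensity scale of the input.
coif1_filters <- function() {
  dec_lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
  dec_hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
              0.3848648468648578, 0.07273261951252645, -0.015655728135791993)
  list(L = dec_lo / sqrt(2), H = dec_hi / sqrt(2), offsets = -2:3)
}

#' Single-level undecimated 3D wavelet decomposition
#'
#' Applies the Coiflet-1 low-pass (L) or high-pass (H) analysis filter along
#' each axis in turn, yielding the 8 sub-bands LLL...HHH. Sub-band labels
#' follow axis order (x, y, z): `"LLH"` is low-pass along x and y, high-pass
#' along z. The transform is undecimated, so every sub-band keeps the input
#' shape, and linear. Boundaries are mirror-extended.
#'
#' @param img a [gx_image].
#' @return Named list of 8 [gx_image] sub-bands.
#' @export
wavelet_decompose <- function(img) {
  f <- coif1_filters()
  labels <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- vector("list", 8L)
  names(out) <- labels
  for (lab in labels) {
    v <- img$values
    sel <- strsplit(lab, "")[[1]]
    for (a in 1:3) v <- filter_axis(v, f[[sel[a]]], f$offsets, a)
    out[[lab]] <- gx_image(v, img$spacing, img$modality)
  }
  out
}
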