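#' Discretize in-mask intensities into equal-width gray levels
#'
#' Bins the in-mask voxel intensities into `n_bins` equal-width bins spanning
#' their range, producing contiguous integer levels 1..Ng. A constant region
#' collapses to a single level. This is the prerequisite of all texture-matrix
#' classes.
#'
#' @param img a [gx_image] or numeric 3D array.
#' @param mask logical array of the same dimensions; must be nonempty.
#' @param n_bins number of bins (>= 2).
#' @return Object of class `gx_discretized`: `levels` (integer array, `NA`
#'   outside the mask), `mask`, `n_levels`, `edges`, `spacing`.
#' @export
discretize <- function(img, mask, n_bins = 32L) {
  v <- if (inherits(img, "gx_image")) img$values else img
  spacing <- if (inherits(img, "gx_image")) img$spacing else c(1, 1, 1)
  if (is.matrix(v)) v <- array(v, c(dim(v), 1L))
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  mask <- array(as.logical(mask), dim(v))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  x <- v[mask]
  lev <- array(NA_integer_, dim(v))
  rng <- range(x)
  if (diff(rng) == 0) {
    lev[mask] <- 1L
    ng <- 1L
    edges <- rng
  } else {
    width <- diff(rng) / n_bins
    lev[mask] <- pmin(as.integer(floor((x - rng[1]) / width)) + 1L,
                      as.integer(n_bins))
    ng <- as.integer(n_bins)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  structure(list(levels = lev, mask = mask, n_levels = ng, edges = edges,
                 spacing = spacing),
            class = "gx_discretized")
}

#' First-order intensity statistics over a masked region
#'
#' Computes the standard first-order radiomics class over in-mask voxels:
#' location (Mean, Median, percentiles), dispersion (Variance, MAD, robust
#' MAD, Range, IQR), shape of the distribution (Skewness, Kurtosis, both
#' population moments), energy measures, and histogram-based Entropy and
#' Uniformity (equal-width bins over the in-mask range). Percentiles use the
#' linear-interpolation convention. Moment ratios on (near-)constant regions
#' are flagged undefined (`NA`), never propagated as `NaN`.
#'
#' @param img a [gx_image] or numeric array.
#' @param mask logical array.
#' @param n_bins histogram bins for Entropy/Uniformity.
#' @return Named numeric vector of features.
#' @export
first_order_features <- function(img, mask, n_bins = 32L) {
  v <- if (inherits(img, "gx_image")) img$values else img
  spacing <- if (inherits(img, "gx_image")) img$spacing else c(1, 1, 1)
  x <- v[as.logical(mask)]
  n <- length(x)
  if (!n) stop("mask is empty", call. = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- unname(stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  inner <- x[x >= q[1] & x <= q[5]]
  # histogram probabilities on the discretized levels
  p <- if (diff(range(x)) == 0) 1 else {
    lv <- discretize(array(x, c(n, 1, 1)), array(TRUE, c(n, 1, 1)), n_bins)
    tabulate(lv$levels[lv$mask], nbins = lv$n_levels) / n
  }
  p_pos <- p[p > 0]
  c(Mean = mu,
    Median = q[3],
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    InterquartileRange = q[4] - q[2],
    Variance = m2,
    StandardDeviation = sqrt(m2),
    Skewness = if (m2 > 1e-30) mean((x - mu)^3) / m2^1.5 else NA_real_,
    Kurtosis = if (m2 > 1e-30) mean((x - mu)^4) / m2^2 else NA_real_,
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    Energy = sum(x^2),
    TotalEnergy = prod(spacing) * sum(x^2),
    RootMeanSquared = sqrt(mean(x^2)),
    Entropy = -sum(p_pos * log2(p_pos)),
    Uniformity = sum(p^2))
}

# Deterministic quasi-uniform directions on the half-sphere (for approximate
# maximum-diameter search on large boundaries).
fibonacci_directions <- function(k) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - i / k)             # polar angle over half sphere
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shape features of a binary mask
#'
#' Volume and surface descriptors computed on the original mask geometry:
#' voxel volume, voxel-face surface area, sphericity, surface/volume ratio,
#' PCA axis lengths (4 * sqrt(eigenvalue) of the voxel-coordinate covariance,
#' in mm), elongation, flatness, and the maximum 3D diameter between boundary
#' voxel centers (exact for up to 2000 boundary voxels, support-point
#' approximation beyond).
#'
#' @param mask logical array.
#' @param spacing length-3 voxel spacing (mm).
#' @return Named numeric vector of features.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  d <- dim(mask)
  n <- sum(mask)
  vol <- n * prod(spacing)

  # voxel-face surface area: faces adjacent to outside-mask or grid boundary
  area <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  for (a in 1:3) {
    shift_out <- function(dir) {
      idx <- which(mask, arr.ind = TRUE)
      nb <- idx
      nb[, a] <- nb[, a] + dir
      inside <- nb[, a] >= 1 & nb[, a] <= d[a]
      exposed <- !inside
      nb_in <- nb[inside, , drop = FALSE]
      exposed_in <- !mask[nb_in]
      sum(exposed) + sum(exposed_in)
    }
    area <- area + (shift_out(1L) + shift_out(-1L)) * face_area[a]
  }

  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx - 0.5, 2, spacing, `*`)
  cc <- sweep(coords, 2, colMeans(coords))
  ev <- if (n > 1) sort(eigen(crossprod(cc) / n, symmetric = TRUE)$values,
                        decreasing = TRUE) else c(0, 0, 0)
  ev <- pmax(ev, 0)
  axis_len <- 4 * sqrt(ev)

  # boundary voxels: any 6-neighbour missing
  is_boundary <- rep(FALSE, n)
  pos <- array(FALSE, d)
  pos[mask] <- TRUE
  for (a in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- idx
      nb[, a] <- nb[, a] + dir
      inside <- nb[, a] >= 1 & nb[, a] <= d[a]
      out <- !inside
      out[inside] <- !pos[nb[inside, , drop = FALSE]]
      is_boundary <- is_boundary | out
    }
  }
  bc <- coords[is_boundary, , drop = FALSE]
  if (nrow(bc) == 0) bc <- coords
  if (nrow(bc) > 2000L) {
    dirs <- fibonacci_directions(200L)
    proj <- bc %*% t(dirs)
    keep <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
    bc <- bc[keep, , drop = FALSE]
  }
  max_diam <- if (nrow(bc) > 1) sqrt(max(as.vector(stats::dist(bc))^2)) else 0

  c(VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = (pi^(1 / 3) * (6 * vol)^(2 / 3)) / area,
    MajorAxisLength = axis_len[1],
    MinorAxisLength = axis_len[2],
    LeastAxisLength = axis_len[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_,
    Maximum3DDiameter = max_diam)
}
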