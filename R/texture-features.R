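# Scalar features of one normalized symmetric GLCM (sums to 1).
glcm_features_one <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  if (tot <= 0) return(glcm_feature_names_na())
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(ng) * px); mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  # difference and sum distributions
  kd <- 0:(ng - 1)
  p_diff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * ng)
  p_sum <- vapply(ks, function(k) sum(p[(i + j) == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  da <- sum(kd * p_diff)
  hxy <- ent(p)
  pxy <- outer(px, py)
  hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- ent(pxy)
  hx <- ent(px); hy <- ent(py)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  offdiag <- i != j
  c(Autocorrelation = sum(p * i * j),
    JointAverage = mu_x,
    ClusterProminence = sum(p * (i + j - mu_x - mu_y)^4),
    ClusterShade = sum(p * (i + j - mu_x - mu_y)^3),
    ClusterTendency = sum(p * (i + j - mu_x - mu_y)^2),
    Contrast = sum(p * (i - j)^2),
    Correlation = if (sd_x > 1e-12 && sd_y > 1e-12)
      (sum(p * i * j) - mu_x * mu_y) / (sd_x * sd_y) else NA_real_,
    DifferenceAverage = da,
    DifferenceEntropy = ent(p_diff),
    DifferenceVariance = sum((kd - da)^2 * p_diff),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p[offdiag] / (i[offdiag] - j[offdiag])^2),
    MaximumProbability = max(p),
    SumAverage = sum(ks * p_sum),
    SumEntropy = ent(p_sum),
    SumSquares = sum(p * (i - mu_x)^2))
}

glcm_feature_names_na <- function() {
  nm <- c("Autocorrelation", "JointAverage", "ClusterProminence",
          "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
          "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
          "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Id", "Idm",
          "Idmn", "Idn", "InverseVariance", "MaximumProbability",
          "SumAverage", "SumEntropy", "SumSquares")
  stats::setNames(rep(NA_real_, length(nm)), nm)
}

#' GLCM features, averaged over the 13 directions
#' @param glcm Ng x Ng x 13 array of per-direction symmetric co-occurrence
#'   counts.
#' @return Named numeric vector.
#' @export
glcm_features <- function(glcm) {
  per_dir <- apply(glcm, 3, function(P) glcm_features_one(P))
  if (is.null(dim(per_dir))) per_dir <- matrix(per_dir, nrow = 1)
  rowMeans(per_dir, na.rm = FALSE)
}

# Run-length / size-zone style features from a level x size count matrix.
# `kind` selects the feature-name vocabulary; `n_voxels` normalises the
# percentage feature. Weighted by size^2 / level^2 in the usual combinations.
size_family_features <- function(M, n_voxels, kind = c("glrlm", "glszm")) {
  kind <- match.arg(kind)
  nz <- sum(M)
  gnames <- if (kind == "glrlm") {
    c(SE = "ShortRunEmphasis", LE = "LongRunEmphasis",
      GLN = "GrayLevelNonUniformity", GLNN = "GrayLevelNonUniformityNormalized",
      SN = "RunLengthNonUniformity", SNN = "RunLengthNonUniformityNormalized",
      PC = "RunPercentage", GLV = "GrayLevelVariance", SV = "RunVariance",
      ENT = "RunEntropy", LGL = "LowGrayLevelRunEmphasis",
      HGL = "HighGrayLevelRunEmphasis", SLGL = "ShortRunLowGrayLevelEmphasis",
      SHGL = "ShortRunHighGrayLevelEmphasis",
      LLGL = "LongRunLowGrayLevelEmphasis",
      LHGL = "LongRunHighGrayLevelEmphasis")
  } else {
    c(SE = "SmallAreaEmphasis", LE = "LargeAreaEmphasis",
      GLN = "GrayLevelNonUniformity", GLNN = "GrayLevelNonUniformityNormalized",
      SN = "SizeZoneNonUniformity", SNN = "SizeZoneNonUniformityNormalized",
      PC = "ZonePercentage", GLV = "GrayLevelVariance", SV = "ZoneVariance",
      ENT = "ZoneEntropy", LGL = "LowGrayLevelZoneEmphasis",
      HGL = "HighGrayLevelZoneEmphasis", SLGL = "SmallAreaLowGrayLevelEmphasis",
      SHGL = "SmallAreaHighGrayLevelEmphasis",
      LLGL = "LargeAreaLowGrayLevelEmphasis",
      LHGL = "LargeAreaHighGrayLevelEmphasis")
  }
  if (nz <= 0)
    return(stats::setNames(rep(NA_real_, length(gnames)), unname(gnames)))
  p <- M / nz
  g <- row(M); s <- col(M)
  mu_g <- sum(p * g); mu_s <- sum(p * s)
  p_pos <- p[p > 0]
  vals <- c(
    SE = sum(p / s^2), LE = sum(p * s^2),
    GLN = sum(rowSums(M)^2) / nz, GLNN = sum(rowSums(M)^2) / nz^2,
    SN = sum(colSums(M)^2) / nz, SNN = sum(colSums(M)^2) / nz^2,
    PC = nz / n_voxels,
    GLV = sum(p * (g - mu_g)^2), SV = sum(p * (s - mu_s)^2),
    ENT = -sum(p_pos * log2(p_pos)),
    LGL = sum(p / g^2), HGL = sum(p * g^2),
    SLGL = sum(p / (s^2 * g^2)), SHGL = sum(p * g^2 / s^2),
    LLGL = sum(p * s^2 / g^2), LHGL = sum(p * s^2 * g^2))
  stats::setNames(unname(vals[names(gnames)]), unname(gnames))
}

#' GLRLM features, averaged over the 13 directions
#' @param glrlm Ng x Nr x 13 per-direction run-length counts.
#' @param n_voxels in-mask voxel count (for RunPercentage).
#' @return Named numeric vector.
#' @export
glrlm_features <- function(glrlm, n_voxels) {
  per_dir <- vapply(seq_len(dim(glrlm)[3]), function(k) {
    m <- glrlm[, , k, drop = FALSE]
    dim(m) <- dim(glrlm)[1:2]
    size_family_features(m, n_voxels, "glrlm")
  }, numeric(16))
  rowMeans(per_dir, na.rm = FALSE)
}

#' GLSZM features
#' @param glszm Ng x Ns zone count matrix.
#' @param n_voxels in-mask voxel count.
#' @return Named numeric vector.
#' @export
glszm_features <- function(glszm, n_voxels) {
  size_family_features(matrix(glszm, nrow = nrow(glszm)), n_voxels, "glszm")
}

#' GLDM features
#' @param gldm Ng x Nd dependence count matrix.
#' @return Named numeric vector.
#' @export
gldm_features <- function(gldm) {
  nz <- sum(gldm)
  p <- gldm / nz
  g <- row(gldm); s <- col(gldm)
  mu_g <- sum(p * g); mu_s <- sum(p * s)
  p_pos <- p[p > 0]
  c(SmallDependenceEmphasis = sum(p / s^2),
    LargeDependenceEmphasis = sum(p * s^2),
    GrayLevelNonUniformity = sum(rowSums(gldm)^2) / nz,
    DependenceNonUniformity = sum(colSums(gldm)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(gldm)^2) / nz^2,
    GrayLevelVariance = sum(p * (g - mu_g)^2),
    DependenceVariance = sum(p * (s - mu_s)^2),
    DependenceEntropy = -sum(p_pos * log2(p_pos)),
    LowGrayLevelEmphasis = sum(p / g^2),
    HighGrayLevelEmphasis = sum(p * g^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (s^2 * g^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * g^2 / s^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * s^2 / g^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * s^2 * g^2))
}

#' NGTDM features
#' @param ngtdm Ng x 2 matrix of per-level counts `n` and absolute-difference
#'   sums `s`.
#' @return Named numeric vector (Coarseness, Contrast, Busyness, Complexity,
#'   Strength).
#' @export
ngtdm_features <- function(ngtdm) {
  n_i <- ngtdm[, "n"]; s_i <- ngtdm[, "s"]
  N <- sum(n_i)
  if (N == 0) {
    # no voxel has a valid neighbourhood (e.g. single-voxel region):
    # the class is undefined and flagged as such
    return(c(Coarseness = NA_real_, Contrast = NA_real_,
             Busyness = NA_real_, Complexity = NA_real_,
             Strength = NA_real_))
  }
  p_i <- n_i / N
  lev <- seq_along(p_i)
  act <- which(p_i > 0)
  ngp <- length(act)
  coars_den <- sum(p_i * s_i)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contrast <- if (ngp > 1) {
    pd <- outer(p_i[act], p_i[act]) * outer(lev[act], lev[act], `-`)^2
    sum(pd) / (ngp * (ngp - 1)) * sum(s_i) / N
  } else 0
  busy_den <- sum(abs(outer(lev[act] * p_i[act], lev[act] * p_i[act], `-`)))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  # Complexity and Strength over active level pairs
  cmplx <- 0; strength <- 0
  for (a in act) for (b in act) {
    cmplx <- cmplx + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
      (p_i[a] + p_i[b])
    strength <- strength + (p_i[a] + p_i[b]) * (a - b)^2
  }
  cmplx <- cmplx / N
  strength <- if (sum(s_i) > 0) strength / sum(s_i) else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = cmplx, Strength = strength)
}

#' All texture features from a set of texture matrices
#'
#' Evaluates every implemented GLCM/GLRLM/GLSZM/GLDM/NGTDM feature, prefixing
#' names with the matrix class (e.g. `glszm_LargeAreaLowGrayLevelEmphasis`).
#' Correlation-type features on degenerate (single-level) matrices are flagged
#' undefined (`NA`).
#'
#' @param mats result of [texture_matrices()].
#' @return Named numeric vector over all five classes.
#' @export
texture_features <- function(mats) {
  pre <- function(prefix, v) stats::setNames(v, paste0(prefix, "_", names(v)))
  c(pre("glcm", glcm_features(mats$glcm)),
    pre("glrlm", glrlm_features(mats$glrlm, mats$n_voxels)),
    pre("glszm", glszm_features(mats$glszm, mats$n_voxels)),
    pre("gldm", gldm_features(mats$gldm)),
    pre("ngtdm", ngtdm_features(mats$ngtdm)))
}
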