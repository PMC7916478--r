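# Independent brute-force oracles for the texture machinery: naive nested
# loops, no shared code with the package implementation.

o_offsets <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                   c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                   c(0, 1, 1), c(0, 1, -1),
                   c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

o_in_grid <- function(v, d) all(v >= 1) && all(v <= d)

o_all_neighbors <- function() {
  nb <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    if (!(dx == 0 && dy == 0 && dz == 0))
      nb[[length(nb) + 1L]] <- c(dx, dy, dz)
  nb
}

o_glcm <- function(lev, off, ng) {
  d <- dim(lev)
  P <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    t <- c(i, j, k) + off
    if (!is.na(a) && o_in_grid(t, d)) {
      b <- lev[t[1], t[2], t[3]]
      if (!is.na(b)) {
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  P
}

o_glrlm <- function(lev, off, ng, nr) {
  d <- dim(lev)
  R <- matrix(0, ng, nr)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g <- lev[i, j, k]
    if (is.na(g)) next
    prev <- c(i, j, k) - off
    starts <- !o_in_grid(prev, d) || is.na(lev[prev[1], prev[2], prev[3]]) ||
      lev[prev[1], prev[2], prev[3]] != g
    if (!starts) next
    len <- 1L
    cur <- c(i, j, k) + off
    while (o_in_grid(cur, d) && !is.na(lev[cur[1], cur[2], cur[3]]) &&
           lev[cur[1], cur[2], cur[3]] == g) {
      len <- len + 1L
      cur <- cur + off
    }
    R[g, len] <- R[g, len] + 1
  }
  R
}

o_glszm <- function(lev, ng) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  nbs <- o_all_neighbors()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g <- lev[i, j, k]
    if (is.na(g) || seen[i, j, k]) next
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      for (nb in nbs) {
        w <- v + nb
        if (o_in_grid(w, d) && !seen[w[1], w[2], w[3]] &&
            !is.na(lev[w[1], w[2], w[3]]) && lev[w[1], w[2], w[3]] == g) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(g, size)
  }
  ns <- max(vapply(zones, `[`, 0, 2))
  Z <- matrix(0, ng, ns)
  for (z in zones) Z[z[1], z[2]] <- Z[z[1], z[2]] + 1
  Z
}

o_gldm <- function(lev, ng) {
  d <- dim(lev)
  M <- matrix(0, ng, 27)
  nbs <- o_all_neighbors()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g <- lev[i, j, k]
    if (is.na(g)) next
    dep <- 1L
    for (nb in nbs) {
      w <- c(i, j, k) + nb
      if (o_in_grid(w, d) && !is.na(lev[w[1], w[2], w[3]]) &&
          lev[w[1], w[2], w[3]] == g) dep <- dep + 1L
    }
    M[g, dep] <- M[g, dep] + 1
  }
  M
}

o_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  n_i <- rep(0, ng); s_i <- rep(0, ng)
  nbs <- o_all_neighbors()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g <- lev[i, j, k]
    if (is.na(g)) next
    vals <- c()
    for (nb in nbs) {
      w <- c(i, j, k) + nb
      if (o_in_grid(w, d) && !is.na(lev[w[1], w[2], w[3]]))
        vals <- c(vals, lev[w[1], w[2], w[3]])
    }
    if (length(vals)) {
      n_i[g] <- n_i[g] + 1
      s_i[g] <- s_i[g] + abs(g - mean(vals))
    }
  }
  cbind(n = n_i, s = s_i)
}

# --- feature oracles: direct loop transcriptions of the standard formulas ---

o_glcm_features <- function(P) {
  ng <- nrow(P)
  p <- P / sum(P)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- 0; mu_y <- 0
  for (i in 1:ng) { mu_x <- mu_x + i * px[i]; mu_y <- mu_y + i * py[i] }
  sd_x <- sqrt(sum((1:ng - mu_x)^2 * px))
  sd_y <- sqrt(sum((1:ng - mu_y)^2 * py))
  pd <- rep(0, ng); ps <- rep(0, 2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + p[i, j]
  }
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  acc <- function(f) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) s <- s + f(i, j, p[i, j])
    s
  }
  da <- sum((0:(ng - 1)) * pd)
  hxy <- H(p); hx <- H(px); hy <- H(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  iv <- 0
  for (i in 1:ng) for (j in 1:ng) if (i != j) iv <- iv + p[i, j] / (i - j)^2
  c(Autocorrelation = acc(function(i, j, v) v * i * j),
    JointAverage = mu_x,
    ClusterProminence = acc(function(i, j, v) v * (i + j - mu_x - mu_y)^4),
    ClusterShade = acc(function(i, j, v) v * (i + j - mu_x - mu_y)^3),
    ClusterTendency = acc(function(i, j, v) v * (i + j - mu_x - mu_y)^2),
    Contrast = acc(function(i, j, v) v * (i - j)^2),
    Correlation = if (sd_x > 1e-12 && sd_y > 1e-12)
      (acc(function(i, j, v) v * i * j) - mu_x * mu_y) / (sd_x * sd_y)
      else NA_real_,
    DifferenceAverage = da,
    DifferenceEntropy = H(pd),
    DifferenceVariance = sum(((0:(ng - 1)) - da)^2 * pd),
    JointEnergy = acc(function(i, j, v) v^2),
    JointEntropy = hxy,
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    Id = acc(function(i, j, v) v / (1 + abs(i - j))),
    Idm = acc(function(i, j, v) v / (1 + (i - j)^2)),
    Idmn = acc(function(i, j, v) v / (1 + ((i - j) / ng)^2)),
    Idn = acc(function(i, j, v) v / (1 + abs(i - j) / ng)),
    InverseVariance = iv,
    MaximumProbability = max(p),
    SumAverage = sum((2:(2 * ng)) * ps),
    SumEntropy = H(ps),
    SumSquares = acc(function(i, j, v) v * (i - mu_x)^2))
}

o_size_features <- function(M, n_voxels, kind) {
  nz <- sum(M)
  p <- M / nz
  ng <- nrow(M); ns <- ncol(M)
  sacc <- function(f) {
    s <- 0
    for (g in 1:ng) for (l in 1:ns) s <- s + f(g, l, p[g, l])
    s
  }
  mu_g <- sacc(function(g, l, v) v * g)
  mu_s <- sacc(function(g, l, v) v * l)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  vals <- c(sacc(function(g, l, v) v / l^2),
            sacc(function(g, l, v) v * l^2),
            sum(rowSums(M)^2) / nz, sum(rowSums(M)^2) / nz^2,
            sum(colSums(M)^2) / nz, sum(colSums(M)^2) / nz^2,
            nz / n_voxels,
            sacc(function(g, l, v) v * (g - mu_g)^2),
            sacc(function(g, l, v) v * (l - mu_s)^2),
            H(p),
            sacc(function(g, l, v) v / g^2), sacc(function(g, l, v) v * g^2),
            sacc(function(g, l, v) v / (l^2 * g^2)),
            sacc(function(g, l, v) v * g^2 / l^2),
            sacc(function(g, l, v) v * l^2 / g^2),
            sacc(function(g, l, v) v * l^2 * g^2))
  names(vals) <- if (kind == "glrlm")
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  else
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  vals
}

o_gldm_features <- function(M) {
  nz <- sum(M)
  p <- M / nz
  ng <- nrow(M); nd <- ncol(M)
  sacc <- function(f) {
    s <- 0
    for (g in 1:ng) for (l in 1:nd) s <- s + f(g, l, p[g, l])
    s
  }
  mu_g <- sacc(function(g, l, v) v * g)
  mu_s <- sacc(function(g, l, v) v * l)
  pp <- p[p > 0]
  c(SmallDependenceEmphasis = sacc(function(g, l, v) v / l^2),
    LargeDependenceEmphasis = sacc(function(g, l, v) v * l^2),
    GrayLevelNonUniformity = sum(rowSums(M)^2) / nz,
    DependenceNonUniformity = sum(colSums(M)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(M)^2) / nz^2,
    GrayLevelVariance = sacc(function(g, l, v) v * (g - mu_g)^2),
    DependenceVariance = sacc(function(g, l, v) v * (l - mu_s)^2),
    DependenceEntropy = -sum(pp * log2(pp)),
    LowGrayLevelEmphasis = sacc(function(g, l, v) v / g^2),
    HighGrayLevelEmphasis = sacc(function(g, l, v) v * g^2),
    SmallDependenceLowGrayLevelEmphasis = sacc(function(g, l, v) v / (l^2 * g^2)),
    SmallDependenceHighGrayLevelEmphasis = sacc(function(g, l, v) v * g^2 / l^2),
    LargeDependenceLowGrayLevelEmphasis = sacc(function(g, l, v) v * l^2 / g^2),
    LargeDependenceHighGrayLevelEmphasis = sacc(function(g, l, v) v * l^2 * g^2))
}

o_ngtdm_features <- function(NG) {
  n_i <- NG[, "n"]; s_i <- NG[, "s"]
  N <- sum(n_i)
  p_i <- n_i / N
  act <- which(p_i > 0)
  ngp <- length(act)
  coars_den <- sum(p_i * s_i)
  contrast <- 0
  if (ngp > 1) {
    for (a in act) for (b in act)
      contrast <- contrast + p_i[a] * p_i[b] * (a - b)^2
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s_i) / N
  }
  busy_den <- 0; cmplx <- 0; strength <- 0
  for (a in act) for (b in act) {
    busy_den <- busy_den + abs(a * p_i[a] - b * p_i[b])
    cmplx <- cmplx + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
      (p_i[a] + p_i[b])
    strength <- strength + (p_i[a] + p_i[b]) * (a - b)^2
  }
  c(Coarseness = if (coars_den > 0) 1 / coars_den else 1e6,
    Contrast = contrast,
    Busyness = if (busy_den > 0) sum(p_i * s_i) / busy_den else 0,
    Complexity = cmplx / N,
    Strength = if (sum(s_i) > 0) strength / sum(s_i) else 0)
}

# Full oracle: all five classes on a discretized level array, matching the
# package's naming and direction averaging.
o_texture_features <- function(lev, ng, n_voxels) {
  nr <- max(dim(lev))
  glcm_dir <- lapply(seq_len(nrow(o_offsets)), function(k)
    o_glcm_features(o_glcm(lev, o_offsets[k, ], ng)))
  glcm <- Reduce(`+`, glcm_dir) / length(glcm_dir)
  glrlm_dir <- lapply(seq_len(nrow(o_offsets)), function(k)
    o_size_features(o_glrlm(lev, o_offsets[k, ], ng, nr), n_voxels, "glrlm"))
  glrlm <- Reduce(`+`, glrlm_dir) / length(glrlm_dir)
  glszm <- o_size_features(o_glszm(lev, ng), n_voxels, "glszm")
  gldm <- o_gldm_features(o_gldm(lev, ng))
  ngtdm <- o_ngtdm_features(o_ngtdm(lev, ng))
  c(setNames(glcm, paste0("glcm_", names(glcm))),
    setNames(glrlm, paste0("glrlm_", names(glrlm))),
    setNames(glszm, paste0("glszm_", names(glszm))),
    setNames(gldm, paste0("gldm_", names(gldm))),
    setNames(ngtdm, paste0("ngtdm_", names(ngtdm))))
}

# Random small discretized image fixture.
random_dimg <- function(seed, dims = c(5, 5, 3), ng = 4, mask_frac = 0.85) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  mask <- array(runif(prod(dims)) < mask_frac, dims)
  if (!any(mask)) mask[1] <- TRUE
  lev[!mask] <- NA_integer_
  list(lev = lev, mask = mask, ng = ng)
}

# Wrap a level array as a gx_discretized without re-binning.
as_dimg <- function(lev, mask, ng, spacing = c(1, 1, 1)) {
  structure(list(levels = lev, mask = mask, n_levels = ng,
                 edges = seq(0, ng), spacing = spacing),
            class = "gx_discretized")
}
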