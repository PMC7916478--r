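# The 13 unique 3D direction offsets (distance-1 neighbours up to sign).
direction_offsets_3d <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# Index ranges of the source block for an offset, or NULL if the offset does
# not fit inside the grid.
offset_ranges <- function(d, off) {
  lo <- pmax(1, 1 - off)
  hi <- pmin(d, d - off)
  if (any(lo > hi)) return(NULL)
  list(r1 = lo[1]:hi[1], r2 = lo[2]:hi[2], r3 = lo[3]:hi[3])
}

# Crop a discretized image to the bounding box of its mask (texture matrices
# only see in-mask voxels; cropping just saves work).
crop_to_mask <- function(lev, mask) {
  rng <- lapply(1:3, function(a) {
    pr <- apply(mask, a, any)
    range(which(pr))
  })
  list(lev = lev[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
                 rng[[3]][1]:rng[[3]][2], drop = FALSE],
       mask = mask[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
                   rng[[3]][1]:rng[[3]][2], drop = FALSE])
}

# Aligned voxel pairs for one offset: (a, b) level vectors over valid pairs.
offset_pairs <- function(lev, off) {
  rr <- offset_ranges(dim(lev), off)
  if (is.null(rr)) return(list(a = integer(), b = integer()))
  a <- lev[rr$r1, rr$r2, rr$r3]
  b <- lev[rr$r1 + off[1], rr$r2 + off[2], rr$r3 + off[3]]
  keep <- !is.na(a) & !is.na(b)
  list(a = a[keep], b = b[keep])
}

glcm_matrix <- function(lev, ng, offsets) {
  out <- array(0, c(ng, ng, nrow(offsets)))
  for (k in seq_len(nrow(offsets))) {
    pr <- offset_pairs(lev, offsets[k, ])
    if (length(pr$a)) {
      counts <- matrix(tabulate((pr$a - 1L) * ng + pr$b, nbins = ng * ng),
                       ng, ng)
      out[, , k] <- counts + t(counts)   # symmetric co-occurrences
    }
  }
  out
}

glrlm_matrix <- function(lev, ng, offsets) {
  d <- dim(lev)
  nr <- max(d)
  out <- array(0, c(ng, nr, nrow(offsets)))
  idx_all <- arrayInd(seq_along(lev), d)
  for (k in seq_len(nrow(offsets))) {
    off <- offsets[k, ]
    # chain starts: voxels whose predecessor falls outside the grid
    prev <- sweep(idx_all, 2, off, `-`)
    start <- prev[, 1] < 1 | prev[, 1] > d[1] | prev[, 2] < 1 |
      prev[, 2] > d[2] | prev[, 3] < 1 | prev[, 3] > d[3]
    pos <- idx_all[start, , drop = FALSE]
    nchain <- nrow(pos)
    steps <- max(d) + 1L            # +1 NA column separates chains
    seqmat <- matrix(NA_integer_, nchain, steps)
    cur <- pos
    for (t in seq_len(steps - 1L)) {
      inside <- cur[, 1] >= 1 & cur[, 1] <= d[1] & cur[, 2] >= 1 &
        cur[, 2] <= d[2] & cur[, 3] >= 1 & cur[, 3] <= d[3]
      if (!any(inside)) break
      lin <- cur[inside, 1] + (cur[inside, 2] - 1L) * d[1] +
        (cur[inside, 3] - 1L) * d[1] * d[2]
      seqmat[inside, t] <- lev[lin]
      cur[, 1] <- cur[, 1] + off[1]
      cur[, 2] <- cur[, 2] + off[2]
      cur[, 3] <- cur[, 3] + off[3]
    }
    r <- rle(as.vector(t(seqmat)))  # NA separators keep chains apart
    keep <- !is.na(r$values) & r$lengths <= nr
    if (any(keep)) {
      g <- r$values[keep]
      l <- r$lengths[keep]
      out[, , k] <- out[, , k] +
        matrix(tabulate((l - 1L) * ng + g, nbins = ng * nr), ng, nr)
    }
  }
  out
}

# Like offset_pairs but returns vertex ids for pairs with EQUAL level.
offset_pairs_ids <- function(lev, vid, off) {
  rr <- offset_ranges(dim(lev), off)
  if (is.null(rr)) return(list(a = integer(), b = integer()))
  a <- lev[rr$r1, rr$r2, rr$r3]
  b <- lev[rr$r1 + off[1], rr$r2 + off[2], rr$r3 + off[3]]
  ia <- vid[rr$r1, rr$r2, rr$r3]
  ib <- vid[rr$r1 + off[1], rr$r2 + off[2], rr$r3 + off[3]]
  keep <- !is.na(a) & !is.na(b) & a == b
  list(a = ia[keep], b = ib[keep])
}

glszm_matrix <- function(lev, ng) {
  mask_lin <- which(!is.na(lev))
  nmv <- length(mask_lin)
  vid <- array(NA_integer_, dim(lev))
  vid[mask_lin] <- seq_len(nmv)
  offs <- direction_offsets_3d()
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    pr_ids <- offset_pairs_ids(lev, vid, offs[k, ])
    if (length(pr_ids$a)) edges[[length(edges) + 1L]] <- cbind(pr_ids$a, pr_ids$b)
  }
  em <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2)
  g <- igraph::make_graph(t(em), n = nmv, directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  levels_of <- lev[mask_lin]
  comp_level <- vapply(seq_along(sizes), function(c)
    levels_of[match(c, comp$membership)], numeric(1))
  ns <- max(sizes)
  out <- matrix(0, ng, ns)
  for (c in seq_along(sizes))
    out[comp_level[c], sizes[c]] <- out[comp_level[c], sizes[c]] + 1
  out
}

gldm_matrix <- function(lev, ng) {
  d <- dim(lev)
  dep_count <- array(0L, d)
  offs <- direction_offsets_3d()
  for (k in seq_len(nrow(offs))) {
    for (sgn in c(1L, -1L)) {
      o <- offs[k, ] * sgn
      rr <- offset_ranges(d, o)
      if (is.null(rr)) next
      a <- lev[rr$r1, rr$r2, rr$r3]
      b <- lev[rr$r1 + o[1], rr$r2 + o[2], rr$r3 + o[3]]
      inc <- array(0L, dim(a))
      inc[!is.na(a) & !is.na(b) & a == b] <- 1L
      dep_count[rr$r1, rr$r2, rr$r3] <- dep_count[rr$r1, rr$r2, rr$r3] + inc
    }
  }
  inm <- !is.na(lev)
  dep <- dep_count[inm] + 1L          # dependence size includes the voxel
  g <- lev[inm]
  out <- matrix(0, ng, 27L)
  for (q in seq_along(g)) out[g[q], dep[q]] <- out[g[q], dep[q]] + 1
  out
}

ngtdm_matrix <- function(lev, ng) {
  d <- dim(lev)
  val <- ifelse(is.na(lev), 0, lev)
  inm <- !is.na(lev)
  nb_sum <- array(0, d)
  nb_cnt <- array(0, d)
  offs <- direction_offsets_3d()
  for (k in seq_len(nrow(offs))) {
    for (sgn in c(1L, -1L)) {
      o <- offs[k, ] * sgn
      rr <- offset_ranges(d, o)
      if (is.null(rr)) next
      nb_sum[rr$r1, rr$r2, rr$r3] <- nb_sum[rr$r1, rr$r2, rr$r3] +
        val[rr$r1 + o[1], rr$r2 + o[2], rr$r3 + o[3]]
      nb_cnt[rr$r1, rr$r2, rr$r3] <- nb_cnt[rr$r1, rr$r2, rr$r3] +
        inm[rr$r1 + o[1], rr$r2 + o[2], rr$r3 + o[3]]
    }
  }
  keep <- inm & nb_cnt > 0
  g <- lev[keep]
  absdiff <- abs(g - nb_sum[keep] / nb_cnt[keep])
  n_i <- tabulate(g, nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) sum(absdiff[g == i]), numeric(1))
  cbind(n = n_i, s = s_i)
}

#' Compute all gray-level texture matrices of a discretized region
#'
#' Returns the five standard texture-matrix summaries of the masked,
#' discretized image: symmetric distance-1 GLCMs over the 13 unique 3D
#' directions (kept per direction for angle-averaged features), GLRLMs per
#' direction, the GLSZM over 26-connected equal-level zones, the GLDM with
#' dependence threshold alpha = 0 over the 26-neighbourhood (dependence size
#' counts the voxel itself plus its equal-level in-mask neighbours), and the
#' NGTDM intermediate sums over 26-neighbourhood means. On single-slice input
#' the 3D neighbourhoods reduce to their in-plane (8-connected) counterparts.
#'
#' @param dimg a [discretize()]d image.
#' @return List with elements `glcm` (Ng x Ng x 13), `glrlm` (Ng x Nr x 13),
#'   `glszm` (Ng x Ns), `gldm` (Ng x 27), `ngtdm` (Ng x 2: counts, sums),
#'   `n_voxels`, `n_levels`.
#' @export
texture_matrices <- function(dimg) {
  stopifnot(inherits(dimg, "gx_discretized"))
  cr <- crop_to_mask(dimg$levels, dimg$mask)
  lev <- cr$lev
  ng <- dimg$n_levels
  offs <- direction_offsets_3d()
  list(glcm = glcm_matrix(lev, ng, offs),
       glrlm = glrlm_matrix(lev, ng, offs),
       glszm = glszm_matrix(lev, ng),
       gldm = gldm_matrix(lev, ng),
       ngtdm = ngtdm_matrix(lev, ng),
       n_voxels = sum(cr$mask), n_levels = ng)
}
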