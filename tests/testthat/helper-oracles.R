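# Independent brute-force oracles for the texture-matrix builders and the
# matrix-feature formulas. Everything here is naive enumeration in plain R,
# deliberately sharing no code with the package's builders.

# All 26 ordered neighbor offsets at Chebyshev distance 1.
oracle_offsets26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

# One offset per antipodal pair (13 directions), chosen by lexicographic
# positivity on (dx, dy, dz).
oracle_offsets13 <- function() {
  off <- oracle_offsets26()
  keep <- apply(off, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  off[keep, , drop = FALSE]
}

# GLCM by enumerating every ordered voxel pair over the 26 offsets; equals
# the symmetrized merged 13-direction accumulation.
oracle_glcm <- function(lev, G) {
  d <- dim(lev)
  off <- oracle_offsets26()
  M <- matrix(0, G, G)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    li <- lev[x, y, z]
    if (li == 0) next
    for (r in seq_len(nrow(off))) {
      xx <- x + off[r, 1]; yy <- y + off[r, 2]; zz <- z + off[r, 3]
      if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3])
        next
      lj <- lev[xx, yy, zz]
      if (lj == 0) next
      M[li, lj] <- M[li, lj] + 1
    }
  }
  M / sum(M)
}

# GLRLM by walking whole lattice lines per direction and run-length encoding
# the level sequence (zeros break runs).
oracle_glrlm <- function(lev, G) {
  d <- dim(lev)
  off <- oracle_offsets13()
  runs <- list()
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      p <- c(x, y, z)
      if (inb(p - o)) next  # not a line start
      seqv <- integer(0)
      while (inb(p)) {
        seqv <- c(seqv, lev[p[1], p[2], p[3]])
        p <- p + o
      }
      rl <- rle(seqv)
      for (i in seq_along(rl$values))
        if (rl$values[i] > 0)
          runs[[length(runs) + 1L]] <- c(rl$values[i], rl$lengths[i])
    }
  }
  rmax <- max(vapply(runs, `[`, 0L, 2))
  M <- matrix(0, G, rmax)
  for (rn in runs) M[rn[1], rn[2]] <- M[rn[1], rn[2]] + 1
  M
}

# GLSZM via repeated dilation region growing (26-connectivity).
oracle_glszm <- function(lev, G) {
  d <- dim(lev)
  off <- oracle_offsets26()
  visited <- array(FALSE, d)
  zones <- list()
  idx <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (visited[p0[1], p0[2], p0[3]]) next
    li <- lev[p0[1], p0[2], p0[3]]
    zone <- matrix(p0, 1, 3)
    visited[p0[1], p0[2], p0[3]] <- TRUE
    frontier <- zone
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (fr in seq_len(nrow(frontier))) {
        for (o in seq_len(nrow(off))) {
          q <- frontier[fr, ] + off[o, ]
          if (any(q < 1) || any(q > d)) next
          if (visited[q[1], q[2], q[3]]) next
          if (lev[q[1], q[2], q[3]] != li) next
          visited[q[1], q[2], q[3]] <- TRUE
          nxt <- rbind(nxt, q)
        }
      }
      if (is.null(nxt)) break
      zone <- rbind(zone, nxt)
      frontier <- nxt
    }
    zones[[length(zones) + 1L]] <- c(li, nrow(zone))
  }
  zmax <- max(vapply(zones, `[`, 0, 2))
  M <- matrix(0, G, zmax)
  for (zn in zones) M[zn[1], zn[2]] <- M[zn[1], zn[2]] + 1
  M
}

# NGTDM by direct per-voxel neighborhood loops.
oracle_ngtdm <- function(lev, G) {
  d <- dim(lev)
  off <- oracle_offsets26()
  n <- numeric(G); s <- numeric(G)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    li <- lev[x, y, z]
    if (li == 0) next
    nb <- numeric(0)
    for (r in seq_len(nrow(off))) {
      xx <- x + off[r, 1]; yy <- y + off[r, 2]; zz <- z + off[r, 3]
      if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3])
        next
      lj <- lev[xx, yy, zz]
      if (lj > 0) nb <- c(nb, lj)
    }
    if (length(nb) > 0) {
      n[li] <- n[li] + 1
      s[li] <- s[li] + abs(li - mean(nb))
    }
  }
  list(n = n, s = s)
}

# Naive double-loop matrix-feature formulas (no vectorized shortcuts).
oracle_glcm_features <- function(P) {
  G <- nrow(P)
  energy <- 0; contrast <- 0; entropy <- 0; homog <- 0; sumavg <- 0
  dissim <- 0
  mu <- 0
  for (i in 1:G) for (j in 1:G) mu <- mu + i * P[i, j]
  s2 <- 0
  for (i in 1:G) for (j in 1:G) s2 <- s2 + (i - mu)^2 * P[i, j]
  corr <- 0
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    energy <- energy + p^2
    contrast <- contrast + (i - j)^2 * p
    if (p > 0) entropy <- entropy - p * log2(p)
    homog <- homog + p / (1 + abs(i - j))
    sumavg <- sumavg + (i + j) * p
    dissim <- dissim + abs(i - j) * p
    if (s2 > 0) corr <- corr + (i - mu) * (j - mu) * p / s2
  }
  c(GLCM_Energy = energy, GLCM_Contrast = contrast, GLCM_Entropy = entropy,
    GLCM_Homogeneity = homog, GLCM_Correlation = corr,
    GLCM_SumAverage = sumavg, GLCM_Variance = s2,
    GLCM_Dissimilarity = dissim)
}

oracle_rl_features <- function(M, slots, prefix, szm = FALSE) {
  G <- nrow(M); R <- ncol(M)
  ns <- sum(M)
  sre <- lre <- gln <- rln <- lgre <- hgre <- 0
  srlge <- srhge <- lrlge <- lrhge <- 0
  for (i in 1:G) {
    ri <- 0
    for (j in 1:R) ri <- ri + M[i, j]
    gln <- gln + ri^2
    lgre <- lgre + ri / i^2
    hgre <- hgre + ri * i^2
  }
  for (j in 1:R) {
    rj <- 0
    for (i in 1:G) rj <- rj + M[i, j]
    rln <- rln + rj^2
    sre <- sre + rj / j^2
    lre <- lre + rj * j^2
  }
  for (i in 1:G) for (j in 1:R) {
    srlge <- srlge + M[i, j] / (i^2 * j^2)
    srhge <- srhge + M[i, j] * i^2 / j^2
    lrlge <- lrlge + M[i, j] * j^2 / i^2
    lrhge <- lrhge + M[i, j] * i^2 * j^2
  }
  mi <- 0; mj <- 0
  for (i in 1:G) for (j in 1:R) {
    mi <- mi + i * M[i, j] / ns
    mj <- mj + j * M[i, j] / ns
  }
  glv <- 0; rlv <- 0
  for (i in 1:G) for (j in 1:R) {
    glv <- glv + (i - mi)^2 * M[i, j] / ns
    rlv <- rlv + (j - mj)^2 * M[i, j] / ns
  }
  nms <- if (szm) c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
                    "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV")
  else c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE", "SRLGE",
         "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV")
  vals <- c(sre / ns, lre / ns, gln / ns, rln / ns, ns / slots, lgre / ns,
            hgre / ns, srlge / ns, srhge / ns, lrlge / ns, lrhge / ns,
            glv, rlv)
  setNames(vals, paste0(prefix, "_", nms))
}

oracle_ngtdm_features <- function(tab, G, eps = 1e-12) {
  n <- tab$n; s <- tab$s
  N <- sum(n)
  p <- n / N
  pres <- which(p > 0)
  coarse <- 1 / (eps + sum(p * s))
  contrast <- 0; busyden <- 0; complexity <- 0; strength <- 0
  if (length(pres) > 1) {
    for (i in pres) for (j in pres) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
      busyden <- busyden + abs(i * p[i] - j * p[j])
      complexity <- complexity +
        abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (N * (p[i] + p[j]))
      strength <- strength + (p[i] + p[j]) * (i - j)^2
    }
    contrast <- contrast / (length(pres) * (length(pres) - 1)) * sum(s) / N
    strength <- strength / (eps + sum(s))
  }
  busy <- if (busyden > 0) sum(p * s) / busyden else 0
  c(NGTDM_Coarseness = coarse, NGTDM_Contrast = contrast,
    NGTDM_Busyness = busy, NGTDM_Complexity = complexity,
    NGTDM_Strength = strength)
}

# Exhaustive pair-counting AUC for <= 10 samples.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Exhaustive boundary-search scalar quantizer MSE for G = 2 (all single
# boundaries between adjacent distinct values, conditional-mean
# reconstruction).
oracle_best_mse_g2 <- function(v) {
  u <- sort(unique(v))
  best <- Inf
  for (i in seq_len(length(u) - 1)) {
    thr <- (u[i] + u[i + 1]) / 2
    lo <- v[v <= thr]; hi <- v[v > thr]
    mse <- (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) / length(v)
    best <- min(best, mse)
  }
  best
}

# helper: wrap a plain integer level array (0 = outside mask) as a
# quantized_roi container so the matrix builders can consume it directly.
levels_to_qroi <- function(lev, G = max(lev)) {
  stopifnot(all(lev >= 0), all(lev <= G))
  structure(list(levels = array(as.integer(lev), dim(lev)),
                 n_levels = as.integer(G), quantizer = "uniform",
                 spacing_mm = c(1, 1, 1), collewet_applied = FALSE,
                 source_stats = c(mu = NA_real_, sigma = NA_real_),
                 representatives = NULL, mse = NA_real_),
            class = "quantized_roi")
}

# random level array fixture (0 sprinkled as out-of-mask)
random_levels <- function(dims, G, p_mask = 0.85) {
  array(sample(0:G, prod(dims), replace = TRUE,
               prob = c(1 - p_mask, rep(p_mask / G, G))),
        dim = dims)
}
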