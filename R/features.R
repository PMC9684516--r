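## Radiomic feature extraction from a quantized ROI. The roster is the
## field-standard 42: 3 first-order ("Global") features on the continuous
## in-ROI intensities, 8 GLCM, 13 GLRLM, 13 GLSZM and 5 NGTDM features from
## the texture matrices, plus 6 volume-normalized (VN) variants and the
## physical ROI volume — 49 named values in total. GLCM/GLRLM aggregate the
## 13 unique 3D directions at distance 1 and are merged across directions
## before normalization; GLSZM zones and NGTDM neighborhoods use
## 26-connectivity and are mask-aware. NGTDM Coarseness and Strength follow
## Amadasun & King; the remaining matrix features follow the IBSI formulas.

#' Names of the 42 base radiomic features
#' @return character vector of length 42.
#' @export
base_feature_names <- function() {
  c(paste0("Global_", c("Variance", "Skewness", "Kurtosis")),
    paste0("GLCM_", c("Energy", "Contrast", "Entropy", "Homogeneity",
                      "Correlation", "SumAverage", "Variance",
                      "Dissimilarity")),
    paste0("GLRLM_", c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                       "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV")),
    paste0("GLSZM_", c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
                       "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV")),
    paste0("NGTDM_", c("Coarseness", "Contrast", "Busyness", "Complexity",
                       "Strength")))
}

#' Names of the 6 volume-normalized feature variants
#' @export
vn_feature_names <- function() {
  c("NGTDM_Strength_VN", "NGTDM_Busyness_VN", "NGTDM_Coarseness_VN",
    "GLSZM_GLN_VN", "GLRLM_GLN_VN", "GLRLM_RLN_VN")
}

#' The full 49-name feature roster (base + VN + volume)
#' @export
feature_names <- function() {
  c(base_feature_names(), vn_feature_names(), "Prostate_Volume")
}

#' Build the four texture matrices from a quantized ROI
#'
#' @param q a `quantized_roi` (see [quantize_uniform()]).
#' @return list with `glcm` (GxG joint probabilities, symmetric, summing to
#'   1), `glrlm` (GxR run counts over 13 directions), `glszm` (GxZ
#'   26-connected zone counts), `ngtdm` (per-level `n`, `s`), and `n_voxels`.
#' @export
build_texture_matrices <- function(q) {
  if (!inherits(q, "quantized_roi")) stop("`q` must be a quantized_roi")
  nv <- sum(q$levels > 0)
  if (nv < 2L) stop("texture matrices need at least 2 in-mask voxels")
  dims <- as.integer(dim(q$levels))
  G <- q$n_levels
  lev <- as.integer(q$levels)

  counts <- glcm_counts_cpp(lev, dims, G)
  tot <- sum(counts)
  if (tot == 0) stop("no in-mask voxel pairs at distance 1 (GLCM undefined)")
  glcm <- counts / tot

  glrlm <- glrlm_counts_cpp(lev, dims, G)
  keep <- which(colSums(glrlm) > 0)
  glrlm <- glrlm[, seq_len(max(keep)), drop = FALSE]

  zones <- glszm_zones_cpp(lev, dims)
  zmax <- max(zones[, 2])
  glszm <- matrix(0, G, zmax)
  for (r in seq_len(nrow(zones)))
    glszm[zones[r, 1], zones[r, 2]] <- glszm[zones[r, 1], zones[r, 2]] + 1

  ngtdm <- ngtdm_table_cpp(lev, dims, G)

  list(glcm = glcm, glrlm = glrlm, glszm = glszm, ngtdm = ngtdm,
       n_voxels = nv)
}

glcm_features <- function(P) {
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  pi_marg <- rowSums(P)
  mu <- sum(seq_len(G) * pi_marg)
  s2 <- sum((seq_len(G) - mu)^2 * pi_marg)
  pos <- P > 0
  corr <- if (s2 > 0) sum((i - mu) * (j - mu) * P) / s2 else 0
  c(GLCM_Energy = sum(P^2),
    GLCM_Contrast = sum((i - j)^2 * P),
    GLCM_Entropy = -sum(P[pos] * log2(P[pos])),
    GLCM_Homogeneity = sum(P / (1 + abs(i - j))),
    GLCM_Correlation = corr,
    GLCM_SumAverage = sum((i + j) * P),   # = 2 mu for a symmetric matrix
    GLCM_Variance = s2,
    GLCM_Dissimilarity = sum(abs(i - j) * P))
}

## Shared formulas for the run-length and size-zone families: `M` holds
## counts indexed by gray level (rows) and run length / zone size (cols);
## `slots` is the normalizer for RP/ZP (voxels x directions for runs,
## voxels for zones).
rl_family <- function(M, slots, prefix,
                      nms = c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE",
                              "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
                              "GLV", "RLV")) {
  ns <- sum(M)
  G <- nrow(M); R <- ncol(M)
  ivec <- seq_len(G); jvec <- seq_len(R)
  ri <- rowSums(M); rj <- colSums(M)
  p <- M / ns
  mu_i <- sum(ivec * rowSums(p))
  mu_j <- sum(jvec * colSums(p))
  i2 <- ivec^2; j2 <- jvec^2
  vals <- c(
    sum(rj / j2) / ns,
    sum(rj * j2) / ns,
    sum(ri^2) / ns,
    sum(rj^2) / ns,
    ns / slots,
    sum(ri / i2) / ns,
    sum(ri * i2) / ns,
    sum(M / outer(i2, j2)) / ns,
    sum((M * outer(i2, 1 / j2))) / ns,
    sum((M * outer(1 / i2, j2))) / ns,
    sum((M * outer(i2, j2))) / ns,
    sum(rowSums(p) * (ivec - mu_i)^2),
    sum(colSums(p) * (jvec - mu_j)^2))
  stats::setNames(vals, paste0(prefix, "_", nms))
}

ngtdm_features <- function(ngt, G, eps = 1e-12) {
  n_i <- ngt$n
  s_i <- ngt$s
  N <- sum(n_i)
  p_i <- n_i / N
  pres <- which(p_i > 0)
  Ngp <- length(pres)
  lev <- seq_len(G)
  ps <- sum(p_i * s_i)
  coarse <- 1 / (eps + ps)
  if (Ngp > 1) {
    pp <- outer(p_i[pres], p_i[pres])
    dd <- outer(lev[pres], lev[pres], "-")
    contrast <- (sum(pp * dd^2) / (Ngp * (Ngp - 1))) * (sum(s_i) / N)
    ip <- lev[pres] * p_i[pres]
    busy_den <- sum(abs(outer(ip, ip, "-")))
    busy <- if (busy_den > 0) ps / busy_den else 0
    psum <- outer(p_i[pres], p_i[pres], "+")
    xsum <- outer(p_i[pres] * s_i[pres], p_i[pres] * s_i[pres], "+")
    complexity <- sum(abs(dd) * xsum / (N * psum))
    strength <- sum(psum * dd^2) / (eps + sum(s_i))
  } else {
    contrast <- 0; busy <- 0; complexity <- 0; strength <- 0
  }
  c(NGTDM_Coarseness = coarse, NGTDM_Contrast = contrast,
    NGTDM_Busyness = busy, NGTDM_Complexity = complexity,
    NGTDM_Strength = strength)
}

global_features <- function(v) {
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  c(Global_Variance = m2,
    Global_Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Global_Kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

#' Fill the volume-normalized feature variants
#'
#' Normalizations against the ROI voxel count: GLSZM GLN, GLRLM GLN, GLRLM
#' RLN and NGTDM Strength and Busyness are divided by the voxel count;
#' NGTDM Coarseness (which shrinks with region size) is multiplied by it.
#' The exponents are isolated here so the convention lives in one place.
#'
#' @param fv named feature vector containing the base features.
#' @param n_voxels ROI voxel count used for extraction.
#' @return `fv` with the six `*_VN` entries filled.
#' @export
volume_normalize <- function(fv, n_voxels) {
  stopifnot(n_voxels >= 1)
  fv["NGTDM_Strength_VN"] <- fv[["NGTDM_Strength"]] / n_voxels
  fv["NGTDM_Busyness_VN"] <- fv[["NGTDM_Busyness"]] / n_voxels
  fv["NGTDM_Coarseness_VN"] <- fv[["NGTDM_Coarseness"]] * n_voxels
  fv["GLSZM_GLN_VN"] <- fv[["GLSZM_GLN"]] / n_voxels
  fv["GLRLM_GLN_VN"] <- fv[["GLRLM_GLN"]] / n_voxels
  fv["GLRLM_RLN_VN"] <- fv[["GLRLM_RLN"]] / n_voxels
  fv
}

#' Extract the full 49-value radiomic feature vector
#'
#' Global (first-order) features are computed on the continuous in-mask
#' intensities of `vol`; matrix features come from the texture matrices of
#' `q`; volume-normalized variants and the physical ROI volume complete the
#' vector.
#'
#' @param vol an [image_volume()] (re-segmented intensities).
#' @param mask the [roi_mask()] used for quantization (cleaned mask).
#' @param q the `quantized_roi` built from `vol` and `mask`.
#' @return named numeric vector, `length(feature_names())` entries.
#' @export
extract_features <- function(vol, mask, q) {
  check_alignment(vol, mask)
  tm <- build_texture_matrices(q)
  nv <- tm$n_voxels
  v <- vol$values[mask$values]
  fv <- c(global_features(v),
          glcm_features(tm$glcm),
          rl_family(tm$glrlm, nv * 13, "GLRLM"),
          rl_family(tm$glszm, nv, "GLSZM",
                    nms = c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
                            "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV",
                            "ZSV")),
          ngtdm_features(tm$ngtdm, q$n_levels))
  fv <- volume_normalize(fv, nv)
  fv["Prostate_Volume"] <- mask_volume_cc(mask)
  fv <- fv[feature_names()]
  bad <- !is.finite(fv)
  if (any(bad))
    stop("non-finite features for families: ",
         paste(unique(sub("_.*", "", names(fv)[bad])), collapse = ", "))
  fv
}
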