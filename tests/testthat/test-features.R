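test_that("texture matrices equal brute-force enumeration on small ROIs", {
  set.seed(99)
  for (rep in 1:12) {
    dims <- sample(2:5, 3, replace = TRUE)
    G <- sample(2:4, 1)
    lev <- random_levels(dims, G)
    if (sum(lev > 0) < 2) next
    q <- levels_to_qroi(lev, G)
    tm <- build_texture_matrices(q)

    expect_equal(tm$glcm, oracle_glcm(lev, G), tolerance = 1e-12)

    og <- oracle_glrlm(lev, G)
    expect_equal(tm$glrlm[, seq_len(ncol(og)), drop = FALSE], og,
                 ignore_attr = TRUE)
    if (ncol(tm$glrlm) > ncol(og))
      expect_true(all(tm$glrlm[, -seq_len(ncol(og))] == 0))

    oz <- oracle_glszm(lev, G)
    expect_equal(tm$glszm[, seq_len(ncol(oz)), drop = FALSE], oz,
                 ignore_attr = TRUE)

    ot <- oracle_ngtdm(lev, G)
    expect_equal(tm$ngtdm$n, ot$n, ignore_attr = TRUE)
    expect_equal(tm$ngtdm$s, ot$s, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("2x2x1 and checkerboard GLCMs match hand enumeration", {
  # levels [[1,2],[1,2]]: oracle enumeration of ordered pairs
  lev <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
  tm <- build_texture_matrices(levels_to_qroi(lev, 2))
  expect_equal(tm$glcm, oracle_glcm(lev, 2), tolerance = 1e-12)

  # 4x4x1 checkerboard: all in-plane axis-aligned neighbors differ by 1
  lev <- array(0L, c(4, 4, 1))
  for (i in 1:4) for (j in 1:4) lev[i, j, 1] <- 1L + (i + j) %% 2L
  tm <- build_texture_matrices(levels_to_qroi(lev, 2))
  expect_equal(tm$glcm, oracle_glcm(lev, 2), tolerance = 1e-12)
  # hand count: 48 ordered axis-aligned pairs, every one across levels 1|2;
  # 36 ordered diagonal pairs, all equal-level -> contrast = 48/84
  fv <- deltarad:::glcm_features(tm$glcm)
  expect_equal(fv[["GLCM_Contrast"]], 48 / 84)
})

test_that("conservation laws hold for random ROIs", {
  set.seed(5)
  for (rep in 1:8) {
    dims <- sample(3:6, 3, replace = TRUE)
    G <- 4
    lev <- random_levels(dims, G)
    nv <- sum(lev > 0)
    if (nv < 2) next
    tm <- build_texture_matrices(levels_to_qroi(lev, G))
    # GLCM: sums to 1 exactly, symmetric, equal marginals
    expect_equal(sum(tm$glcm), 1, tolerance = 1e-12)
    expect_equal(tm$glcm, t(tm$glcm), tolerance = 1e-15)
    expect_equal(rowSums(tm$glcm), colSums(tm$glcm), tolerance = 1e-15)
    # GLRLM: every voxel is in exactly one run per direction
    expect_equal(sum(tm$glrlm %*% seq_len(ncol(tm$glrlm))), nv * 13)
    # GLSZM: zone sizes partition the ROI
    expect_equal(sum(tm$glszm %*% seq_len(ncol(tm$glszm))), nv)
    # NGTDM: counted voxels cannot exceed ROI voxels; s >= 0
    expect_lte(sum(tm$ngtdm$n), nv)
    expect_true(all(tm$ngtdm$s >= -1e-15))
  }
})

test_that("constant ROI closed forms", {
  lev <- array(1L, c(3, 3, 3))
  vol <- image_volume(array(4.2, c(3, 3, 3)), c(1, 1, 1))
  msk <- roi_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  q <- quantize_uniform(vol, msk, 4)
  tm <- build_texture_matrices(q)
  expect_equal(tm$glcm[1, 1], 1)
  expect_equal(sum(tm$glszm), 1)          # one zone...
  expect_equal(tm$glszm[1, 27], 1)        # ...of size 27 at level 1
  expect_equal(sum(tm$ngtdm$s), 0)

  fv <- extract_features(vol, msk, q)
  expect_equal(fv[["Global_Variance"]], 0)
  expect_equal(fv[["GLCM_Energy"]], 1)
  expect_equal(fv[["GLCM_Contrast"]], 0)
  expect_equal(fv[["NGTDM_Contrast"]], 0)
  expect_true(all(is.finite(fv)))

  # single-voxel ROI: no pairs -> error
  m1 <- roi_mask(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)), c(1, 1, 1))
  expect_error(build_texture_matrices(quantize_uniform(vol, m1, 4)))
})

test_that("feature roster has 42 base names, 49 total", {
  expect_length(base_feature_names(), 42)
  expect_length(feature_names(), 49)
  expect_equal(ceiling(sqrt(length(feature_names()))), 7)
  expect_false(anyDuplicated(feature_names()) > 0)
  # the families split 3 + 8 + 13 + 13 + 5
  fam <- table(sub("_.*", "", base_feature_names()))
  expect_equal(as.integer(fam[c("Global", "GLCM", "GLRLM", "GLSZM",
                                "NGTDM")]), c(3, 8, 13, 13, 5))
})

test_that("every feature matches the naive-formula oracle on a random ROI", {
  set.seed(31)
  dims <- c(8, 8, 8)
  G <- 8
  vals <- array(rnorm(prod(dims)), dims)
  msk <- roi_mask(array(runif(prod(dims)) < 0.9, dims), c(1, 1, 1))
  vol <- image_volume(vals, c(1, 1, 1))
  q <- quantize_uniform(vol, msk, G)
  tm <- build_texture_matrices(q)
  fv <- extract_features(vol, msk, q)
  nv <- tm$n_voxels

  ref <- c(oracle_glcm_features(tm$glcm),
           oracle_rl_features(tm$glrlm, nv * 13, "GLRLM"),
           oracle_rl_features(tm$glszm, nv, "GLSZM", szm = TRUE),
           oracle_ngtdm_features(tm$ngtdm, G))
  for (nm in names(ref))
    expect_equal(fv[[nm]], ref[[nm]], tolerance = 1e-9, label = nm)

  # global features against direct formulas
  v <- vals[msk$values]
  expect_equal(fv[["Global_Variance"]], mean((v - mean(v))^2))
  expect_equal(fv[["Global_Skewness"]],
               mean((v - mean(v))^3) / mean((v - mean(v))^2)^1.5)
  expect_equal(fv[["Global_Kurtosis"]],
               mean((v - mean(v))^4) / mean((v - mean(v))^2)^2 - 3)
})

test_that("volume normalization directions and duplication invariance", {
  fv <- setNames(numeric(length(feature_names())), feature_names())
  fv["NGTDM_Strength"] <- 10; fv["NGTDM_Busyness"] <- 4
  fv["NGTDM_Coarseness"] <- 0.5; fv["GLSZM_GLN"] <- 6
  fv["GLRLM_GLN"] <- 8; fv["GLRLM_RLN"] <- 12
  out <- volume_normalize(fv, 1)
  # n_voxels = 1 is the identity scaling
  expect_equal(out[["NGTDM_Strength_VN"]], 10)
  expect_equal(out[["NGTDM_Coarseness_VN"]], 0.5)
  out2 <- volume_normalize(fv, 10)
  expect_equal(out2[["GLSZM_GLN_VN"]], 0.6)
  expect_equal(out2[["NGTDM_Coarseness_VN"]], 5)

  # duplicating an ROI as two disjoint far-apart copies doubles GLN and the
  # voxel count, leaving GLN-VN approximately invariant
  set.seed(8)
  dims <- c(6, 6, 3)
  vals1 <- array(rnorm(prod(dims)), dims)
  big <- array(rnorm(6 * 6 * 11), c(6, 6, 11))
  big[, , 1:3] <- vals1
  big[, , 9:11] <- vals1
  m1 <- array(FALSE, dims); m1[] <- TRUE
  mbig <- array(FALSE, c(6, 6, 11)); mbig[, , 1:3] <- TRUE; mbig[, , 9:11] <- TRUE
  v1 <- image_volume(vals1, c(1, 1, 1))
  vb <- image_volume(big, c(1, 1, 1))
  q1 <- quantize_uniform(v1, roi_mask(m1, c(1, 1, 1)), 8)
  # quantize the duplicated ROI with the same gray-level mapping by reusing
  # intensities: both copies share min/max so levels agree
  qb <- quantize_uniform(vb, roi_mask(mbig, c(1, 1, 1)), 8)
  f1 <- extract_features(v1, roi_mask(m1, c(1, 1, 1)), q1)
  fb <- extract_features(vb, roi_mask(mbig, c(1, 1, 1)), qb)
  expect_equal(fb[["GLRLM_GLN_VN"]], f1[["GLRLM_GLN_VN"]], tolerance = 0.05)
  expect_equal(fb[["GLSZM_GLN_VN"]], f1[["GLSZM_GLN_VN"]], tolerance = 0.05)
  expect_equal(fb[["GLRLM_RLN_VN"]], f1[["GLRLM_RLN_VN"]], tolerance = 0.05)
})

test_that("quantized levels are invariant to affine intensity maps", {
  set.seed(13)
  vals <- array(rnorm(5^3), c(5, 5, 5))
  msk <- roi_mask(array(TRUE, c(5, 5, 5)), c(1, 1, 1))
  v1 <- image_volume(vals, c(1, 1, 1))
  v2 <- image_volume(3.7 * vals + 11, c(1, 1, 1))
  q1 <- quantize_uniform(v1, msk, 16)
  q2 <- quantize_uniform(v2, msk, 16)
  expect_identical(q1$levels, q2$levels)
})
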