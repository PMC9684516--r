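make_vol <- function(vals, sp = c(1, 1, 1)) image_volume(vals, sp)
full_mask <- function(vals, sp = c(1, 1, 1)) {
  roi_mask(array(TRUE, dim(vals)), sp)
}

test_that("Collewet re-segmentation removes only 3-sigma outliers", {
  # 99 voxels at 0 and one at 1000 in a 10x10x1 slab:
  # mu = 10, population sd = sqrt(99*10^2/100 + 990^2/100) computed by hand
  vals <- array(0, c(10, 10, 1))
  vals[1, 1, 1] <- 1000
  mu <- mean(vals)
  sg <- sqrt(mean((vals - mu)^2))
  expect_equal(mu, 10)
  expect_equal(sg, sqrt((99 * 100 + 990^2) / 100))  # 99.4987...
  vol <- make_vol(vals)
  out <- collewet_resegment(vol, full_mask(vals))
  expect_equal(mask_voxel_count(out), 99)
  expect_false(out$values[1, 1, 1])

  # everything within +-3 sigma (uniform noise) -> unchanged
  u <- array(runif(125), c(5, 5, 5))
  expect_identical(collewet_resegment(make_vol(u), full_mask(u))$values,
                   full_mask(u)$values)

  # constant ROI: sigma = 0 branch, unchanged
  cst <- array(5, c(3, 3, 3))
  expect_identical(collewet_resegment(make_vol(cst), full_mask(cst))$values,
                   full_mask(cst)$values)
  expect_error(collewet_resegment(make_vol(cst),
                                  roi_mask(array(c(TRUE, rep(FALSE, 26)),
                                                 c(3, 3, 3)), c(1, 1, 1))),
               "2 ROI voxels")
})

test_that("Collewet output is a subset of the input mask", {
  set.seed(42)
  for (rep in 1:20) {
    vals <- array(rcauchy(4^3), c(4, 4, 4))  # heavy tails force removals
    m0 <- full_mask(vals)
    m1 <- collewet_resegment(make_vol(vals), m0)
    expect_true(all(m0$values[m1$values]))
    expect_true(all(!m1$values | m0$values))
  }
})

test_that("uniform quantization maps min to 1, max to G, half-open bins", {
  vals <- array(0:255, c(16, 16, 1))
  q <- quantize_uniform(make_vol(vals), full_mask(vals), 256)
  expect_identical(as.integer(q$levels), as.integer(vals + 1L))

  set.seed(7)
  vals <- array(rnorm(200), c(10, 10, 2))
  for (G in c(4, 16, 256)) {
    q <- quantize_uniform(make_vol(vals), full_mask(vals), G)
    lv <- q$levels[q$levels > 0]
    expect_equal(lv[which.min(vals)], 1)
    expect_equal(lv[which.max(vals)], G)
    expect_lte(max(lv), G)
  }

  cst <- array(3.14, c(3, 3, 1))
  q <- quantize_uniform(make_vol(cst), full_mask(cst), 8)
  expect_true(all(q$levels == 1))
  expect_equal(quantization_mse(q), 0)
})

test_that("Lloyd-Max achieves zero MSE when representable and beats uniform", {
  # distinct values <= G -> exact representation
  vals <- array(rep(c(1, 5, 9, 13), 16), c(8, 8, 1))
  q <- quantize_lloyd_max(make_vol(vals), full_mask(vals), 8)
  expect_equal(quantization_mse(q), 0)
  # each distinct value its own level, in ascending order
  expect_equal(sort(unique(as.vector(q$levels[q$levels > 0]))), 1:4)

  # constant ROI -> single level, zero error
  cst <- array(2, c(3, 3, 1))
  qc <- quantize_lloyd_max(make_vol(cst), full_mask(cst), 4)
  expect_true(all(qc$levels == 1))
  expect_equal(quantization_mse(qc), 0)

  # bimodal: Lloyd separates the modes exactly; verified against the
  # exhaustive single-boundary search oracle
  v <- c(rep(0, 900), rep(100, 100))
  vals <- array(v, c(10, 10, 10))
  ql <- quantize_lloyd_max(make_vol(vals), full_mask(vals), 2)
  qu <- quantize_uniform(make_vol(vals), full_mask(vals), 2)
  expect_equal(quantization_mse(ql), 0)
  expect_equal(quantization_mse(ql), oracle_best_mse_g2(v))
  expect_lte(quantization_mse(ql), quantization_mse(qu))

  # trimodal variant: Lloyd never worse than uniform
  # and matches the exhaustive boundary-search optimum
  v <- c(rep(0, 900), rep(60, 50), rep(100, 50))
  vals <- array(v, c(10, 10, 10))
  ql <- quantize_lloyd_max(make_vol(vals), full_mask(vals), 2)
  qu <- quantize_uniform(make_vol(vals), full_mask(vals), 2)
  expect_lte(quantization_mse(ql), quantization_mse(qu) + 1e-12)
  expect_equal(quantization_mse(ql), oracle_best_mse_g2(v), tolerance = 1e-9)
})

test_that("Lloyd-Max MSE <= uniform MSE over random ROIs (property)", {
  set.seed(123)
  for (rep in 1:40) {
    n <- sample(60:400, 1)
    gen <- sample(1:3, 1)
    v <- switch(gen,
                rnorm(n),
                rexp(n),
                c(rnorm(n %/% 2), rnorm(n - n %/% 2, mean = 5)))
    dims <- c(n, 1, 1)
    vol <- make_vol(array(v, dims))
    msk <- full_mask(vol$values)
    for (G in c(4, 16, 256)) {
      ql <- quantize_lloyd_max(vol, msk, G)
      qu <- quantize_uniform(vol, msk, G)
      expect_lte(quantization_mse(ql), quantization_mse(qu) + 1e-10)
    }
  }
})

test_that("fiducial artifact removal catches injected artifacts exactly", {
  cfg <- cohort_config(n_patients = 2, n_fiducials = 2, seed = 11)
  co <- generate_cohort(cfg)
  fr <- generate_phantom_fraction(co[[1]], 1)
  res <- remove_fiducial_artifacts(fr$volume, fr$mask,
                                   fr$fiducial_centers_mm)
  expect_gt(res$removed_fraction, 0)
  expect_lte(res$removed_fraction, 1)

  # recall = 1 for ground-truth artifact voxels inside the 5 mm circle on
  # artifact layers (the only voxels the algorithm is allowed to touch)
  sp <- fr$volume$spacing_mm
  ctr <- fr$fiducial_centers_mm
  av <- fr$artifact_voxels
  n_checked <- 0
  for (r in seq_len(nrow(av))) {
    i <- av[r, 1]; j <- av[r, 2]; k <- av[r, 3]
    if (!fr$mask$values[i, j, k]) next
    pos <- (c(i, j) - 0.5) * sp[1:2]
    zk <- (k - 0.5) * sp[3]
    # circles act per fiducial on the layers that fiducial occupies
    active <- abs(zk - ctr[, 3]) <= 2.5
    in_circle <- any(active &
      sqrt((pos[1] - ctr[, 1])^2 + (pos[2] - ctr[, 2])^2) <= 5)
    if (in_circle) {
      n_checked <- n_checked + 1
      expect_false(res$cleaned_mask$values[i, j, k])
    }
  }
  expect_gt(n_checked, 10)   # the recall claim must actually bite

  # never removes voxels on non-artifact layers
  clean_layers <- setdiff(seq_len(dim(fr$mask$values)[3]),
                          res$artifact_layers)
  expect_identical(res$cleaned_mask$values[, , clean_layers],
                   fr$mask$values[, , clean_layers])
})

test_that("artifact removal degenerate cases", {
  vals <- array(rnorm(4^3), c(4, 4, 4))
  vol <- make_vol(vals)
  msk <- full_mask(vals)
  # no fiducials -> identity
  res <- remove_fiducial_artifacts(vol, msk, NULL)
  expect_identical(res$cleaned_mask$values, msk$values)
  expect_equal(res$removed_fraction, 0)
  res2 <- remove_fiducial_artifacts(vol, msk, matrix(numeric(0), 0, 3))
  expect_equal(res2$removed_fraction, 0)
  # fiducial spanning every layer -> threshold undefined
  ctr <- matrix(c(2, 2, 2), 1, 3)
  expect_error(
    remove_fiducial_artifacts(vol, msk, ctr, fiducial_halflength_mm = 10),
    "threshold")
})
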