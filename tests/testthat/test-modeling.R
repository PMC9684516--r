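test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(compute_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(compute_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(compute_auc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)  # reversed
  expect_equal(compute_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)  # all tied
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(4:10, 1)
    sc <- sample(1:5, n, replace = TRUE)  # many ties
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(compute_auc(sc, y), oracle_auc(sc, y), tolerance = 1e-12)
  }
  expect_error(compute_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("forest ranking is deterministic and finds a planted feature", {
  set.seed(3)
  n <- 80
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("F%02d", 1:10)))
  y <- rbinom(n, 1, 0.5)
  X[, "F03"] <- y                      # exact copy of the labels
  r1 <- rf_gini_importance(X, y, n_trees = 200, seed = 42)
  r2 <- rf_gini_importance(X, y, n_trees = 200, seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$feature[1], "F03")
  expect_true(all(diff(r1$importance) <= 0))
  expect_true(all(r1$importance >= 0))
  expect_error(rf_gini_importance(X, rep(1, n)), "single class")
})

test_that("null labels give no feature an outsized importance", {
  # with y independent of X, each feature's importance should stay below the
  # 95th percentile of a label-permutation null for the bulk of features
  set.seed(10)
  n <- 60; p <- 20
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("F%02d", 1:p)))
  y <- rbinom(n, 1, 0.5)
  obs <- rf_gini_importance(X, y, n_trees = 100, seed = 1)
  null_imp <- unlist(lapply(1:50, function(s) {
    set.seed(1000 + s)
    yp <- sample(y)
    rf_gini_importance(X, yp, n_trees = 100, seed = s)$importance
  }))
  q95 <- quantile(null_imp, 0.95)
  expect_gte(mean(obs$importance <= q95), 0.9)
})

test_that("correlation filter keeps the highest-ranked of correlated sets", {
  set.seed(6)
  n <- 50
  A <- rnorm(n)
  C <- rnorm(n)
  B <- 0.95 * A + sqrt(1 - 0.95^2) * C * 0 + 0.05 * rnorm(n)  # r(A,B) ~ 1
  X <- cbind(A = A, B = B, C = C)
  rk <- data.frame(feature = c("A", "B", "C"), importance = c(3, 2, 1))
  out <- correlation_filter(X, rk, threshold = 0.8)
  expect_identical(out$feature, c("A", "C"))

  # identical features, ranks 1 and 2 -> only rank 1 kept
  X2 <- cbind(A = A, B = A)
  rk2 <- data.frame(feature = c("A", "B"), importance = c(2, 1))
  expect_identical(correlation_filter(X2, rk2)$feature, "A")

  # all pairwise below threshold -> unchanged
  X3 <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  expect_identical(correlation_filter(X3, rk)$feature, rk$feature)

  # hand-traced: r(A,B) = .9, r(A,C) = .5, r(B,C) = .9, order A > B > C
  # greedy keeps A, drops B (corr with A), keeps C (corr .5 with A)
  z1 <- rnorm(n); z2 <- rnorm(n)
  A4 <- z1
  B4 <- 0.9 * scale(z1)[, 1] + sqrt(1 - 0.81) * scale(z2)[, 1]
  C4 <- 0.5 * scale(z1)[, 1] + 0.62 * scale(z2)[, 1] + 0.3 * rnorm(n)
  X4 <- cbind(A = A4, B = B4, C = C4)
  stopifnot(abs(cor(X4[, "A"], X4[, "B"])) > 0.8,
            abs(cor(X4[, "A"], X4[, "C"])) < 0.8,
            abs(cor(X4[, "B"], X4[, "C"])) > 0.8)
  rk4 <- data.frame(feature = c("A", "B", "C"), importance = 3:1)
  expect_identical(correlation_filter(X4, rk4)$feature, c("A", "C"))

  # exempt covariates are always kept and never block others
  rk5 <- data.frame(feature = c("A", "B"), importance = 2:1)
  out5 <- correlation_filter(X2, rk5, exempt = "B")
  expect_identical(out5$feature, c("A", "B"))
})

test_that("selection caps at 7 and breaks Gini ties lexically", {
  rk <- data.frame(feature = sprintf("F%02d", 1:10), importance = 10:1)
  expect_length(select_features(rk), 7)
  rk3 <- data.frame(feature = c("C", "A", "B"), importance = c(1, 1, 1))
  # rf_gini_importance orders ties lexically; select respects that order
  srt <- rk3[order(-rk3$importance, rk3$feature), ]
  expect_identical(select_features(srt, 2), c("A", "B"))
  expect_identical(select_features(rk3[0, ], 7), character(0))
})

test_that("logistic fit handles separation, null data and intercept-only", {
  set.seed(4)
  n <- 40
  x <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
  y <- rep(c(0, 1), each = n / 2)           # perfectly separable
  X <- cbind(F = x)
  fit <- fit_logistic(X, y)
  expect_true(all(is.finite(fit$coefficients)))
  p <- deltarad:::predict_logistic(fit, X)
  expect_equal(compute_auc(p, y), 1)
  expect_true(all(diff(p[order(x)]) >= -1e-12))  # monotone in the feature

  # intercept-only: predicted probability equals class prevalence
  Xc <- cbind(F = rep(1, 30))
  yc <- c(rep(1, 9), rep(0, 21))
  fitc <- fit_logistic(Xc, yc)
  expect_equal(unname(deltarad:::predict_logistic(fitc, Xc)[1]), 0.3,
               tolerance = 1e-6)

  # null: coefficient z-scores behave like a null (sanity via glm agreement)
  Xn <- matrix(rnorm(200 * 2), 200, 2, dimnames = list(NULL, c("a", "b")))
  yn <- rbinom(200, 1, 0.5)
  fitn <- fit_logistic(Xn, yn)
  ref <- glm(yn ~ Xn, family = binomial())
  expect_equal(unname(fitn$coefficients), unname(coef(ref)),
               tolerance = 1e-5)
  expect_error(fit_logistic(Xn, rep(0, 200)), "single class")
})

test_that("null-model coefficients stay near zero across simulations", {
  set.seed(44)
  zs <- replicate(40, {
    X <- matrix(rnorm(200 * 3), 200, 3)
    y <- rbinom(200, 1, 0.5)
    fit <- fit_logistic(X, y)
    ref <- glm(y ~ X, family = binomial())
    max(abs(coef(summary(ref))[-1, "z value"]))
  })
  expect_gte(mean(zs < 3), 0.95)
})

test_that("bootstrap-LOO AUC distribution behaves at the extremes", {
  set.seed(9)
  n <- 20
  x <- c(rnorm(n / 2, -4), rnorm(n / 2, 4))
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(F = x)
  b <- loo_bootstrap_auc(X, y, n_iter = 50, seed = 2)
  expect_true(all(b$auc[!is.na(b$auc)] == 1))   # separable -> AUC 1 always
  expect_equal(b$median, 1)

  # determinism and the alternative LOO-then-bootstrap flavor
  b2 <- loo_bootstrap_auc(X, y, n_iter = 50, seed = 2)
  expect_identical(b$auc, b2$auc)
  b3 <- loo_bootstrap_auc(X, y, n_iter = 50, seed = 2,
                          method = "loo_boot_scores")
  expect_equal(b3$median, 1)
  expect_error(loo_bootstrap_auc(X[1:3, , drop = FALSE], y[1:3]),
               "at least 4")
})

test_that("fit_endpoint_models wires selection and per-bin validation", {
  set.seed(77)
  np <- 24; nb <- 6; nf <- 10
  feats <- sprintf("F%02d", 1:nf)
  A <- array(rnorm(np * nb * nf), c(np, nb, nf),
             dimnames = list(sprintf("P%03d", 1:np), paste0("BED", bed_bins()),
                             feats))
  y <- rbinom(np, 1, 0.5)
  y[1] <- 0; y[2] <- 1
  A[, , 1] <- A[, , 1] + 2 * matrix(y, np, nb)   # informative feature F01
  L <- matrix(y, np, nb, dimnames = dimnames(A)[1:2])
  m <- fit_endpoint_models(A, L, n_trees = 100, n_iter = 30, seed = 5)
  expect_lte(length(m$selected_features), 7)
  expect_true("F01" %in% m$selected_features)
  for (b in names(m$per_bin)) {
    pb <- m$per_bin[[b]]
    expect_true(pb$evaluable)
    expect_true(all(pb$auc >= 0 & pb$auc <= 1, na.rm = TRUE))
    expect_length(pb$auc, 30)
  }
  # survivors pairwise |r| <= 0.8 over the pooled rows
  Xpool <- do.call(rbind, lapply(1:nb, function(b) A[, b, ]))
  sel <- setdiff(m$selected_features, "IPSS_Baseline")
  if (length(sel) > 1) {
    cm <- abs(cor(Xpool[, sel]))
    expect_lte(max(cm[upper.tri(cm)]), 0.8 + 1e-9)
  }
})
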