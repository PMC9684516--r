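## Feature selection and per-bin logistic modeling. All BED bins are pooled
## into one cohort for selection: a 500-tree random forest (2/3 of patients
## per bag, 7 candidate features per split) ranks features by Gini
## importance; strongly correlated features (|Pearson r| > 0.8 over the
## pooled rows) are removed keeping the better-ranked one; at most 7
## survivors enter the per-bin logistic models, which are validated by
## patient-level bootstrap resampling with leave-one-out scoring (1000
## iterations) summarized as an AUC distribution.

#' Random-forest Gini importance ranking
#'
#' @param X numeric matrix (rows = pooled patient-bin observations, named
#'   feature columns).
#' @param y binary labels (0/1), one per row; both classes required.
#' @param n_trees number of trees (default 500).
#' @param features_per_split candidate features per split (default 7).
#' @param bag_fraction fraction of rows per bag, drawn without replacement
#'   (default 2/3).
#' @param seed RNG seed; the ranking is deterministic given the seed.
#' @return data.frame (`feature`, `importance`) sorted by decreasing
#'   importance, ties broken by feature name.
#' @export
rf_gini_importance <- function(X, y, n_trees = 500L, features_per_split = 7L,
                               bag_fraction = 2 / 3, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  set.seed(seed)
  imp <- rf_gini_cpp(X, y, as.integer(n_trees),
                     as.integer(features_per_split), bag_fraction)
  out <- data.frame(feature = colnames(X), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature), , drop = FALSE]
}

#' Drop strongly correlated lower-ranked features
#'
#' Greedy pass from the top of the ranking: a feature is kept iff its
#' absolute Pearson correlation (over all pooled rows) with every
#' already-kept feature is <= `threshold`. Features in `exempt` are always
#' kept and never block others (used for the baseline-IPSS clinical
#' covariate).
#'
#' @param X pooled design matrix with named columns.
#' @param ranking data.frame from [rf_gini_importance()].
#' @param threshold correlation threshold (default 0.8).
#' @param exempt feature names exempt from filtering.
#' @return filtered ranking (same columns, subset of rows).
#' @export
correlation_filter <- function(X, ranking, threshold = 0.8,
                               exempt = character(0)) {
  X <- as.matrix(X)
  keep <- character(0)
  for (f in ranking$feature) {
    if (f %in% exempt) { keep <- c(keep, f); next }
    others <- setdiff(keep, exempt)
    ok <- TRUE
    for (g in others) {
      r <- suppressWarnings(stats::cor(X[, f], X[, g]))
      if (is.finite(r) && abs(r) > threshold) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, f)
  }
  ranking[ranking$feature %in% keep, , drop = FALSE]
}

#' Cap the selection at the top-k surviving features
#' @param filtered ranking after [correlation_filter()].
#' @param max_k maximum number of features (default 7).
#' @return character vector of selected feature names.
#' @export
select_features <- function(filtered, max_k = 7L) {
  utils::head(filtered$feature, max_k)
}

#' Maximum-likelihood logistic fit with a ridge fallback
#'
#' Plain IRLS; if the fit fails to converge or coefficients diverge
#' (complete separation), it is refit with a small ridge penalty
#' (`lambda = 1e-4` on the non-intercept terms) so coefficients stay finite
#' without materially changing the ranking of predictions.
#'
#' @param X design matrix (no intercept column).
#' @param y binary labels.
#' @param lambda ridge penalty (default 0; the fallback uses 1e-4).
#' @param max_iter IRLS iteration cap.
#' @return list with `coefficients` (intercept first), `converged`,
#'   `ridge_used`.
#' @export
fit_logistic <- function(X, y, lambda = 0, max_iter = 50L) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  fit <- irls_logistic(X, y, lambda, max_iter)
  if (!fit$converged || max(abs(fit$beta)) > 30) {
    fit <- irls_logistic(X, y, max(lambda, 1e-4), max_iter)
    fit$ridge_used <- TRUE
  } else {
    fit$ridge_used <- lambda > 0
  }
  nm <- c("(Intercept)", colnames(X))
  list(coefficients = stats::setNames(fit$beta, nm),
       converged = fit$converged, ridge_used = fit$ridge_used)
}

irls_logistic <- function(X, y, lambda, max_iter) {
  Z <- cbind(1, X)
  p <- ncol(Z)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(Z %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Z, y - mu)) - drop(pen %*% beta)
    H <- crossprod(Z * w, Z) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      step <- solve(H + diag(1e-8, p), grad)
    }
    beta <- beta + step
    if (max(abs(step)) < 1e-8) { converged <- TRUE; break }
  }
  list(beta = beta, converged = converged)
}

predict_logistic <- function(fit, X) {
  stats::plogis(drop(cbind(1, as.matrix(X)) %*% fit$coefficients))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score+ > score-) + 0.5 P(tie)`, computed with midranks.
#'
#' @param scores numeric predictions.
#' @param labels binary labels (0/1); both classes required.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap leave-one-out AUC distribution
#'
#' Default method `"bootstrap_loo"`: per iteration a patient-level bootstrap
#' resample (with replacement; both classes enforced by redraw, up to 100
#' attempts) is taken, leave-one-out runs over the resample's unique
#' patients (fit on the remaining resample rows, score the held-out
#' patient's original row), and one AUC is computed from the held-out
#' scores. The alternative `"loo_boot_scores"` runs LOO once on the full
#' cohort and bootstraps the AUC over the held-out score/label pairs.
#'
#' @param X per-bin design matrix (one row per patient, selected features).
#' @param y binary labels.
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @param method `"bootstrap_loo"` (default) or `"loo_boot_scores"`.
#' @return list with `auc` (length `n_iter`), `median`, `ci` (2.5/97.5
#'   percentiles).
#' @export
loo_bootstrap_auc <- function(X, y, n_iter = 1000L, seed = 1L,
                              method = c("bootstrap_loo", "loo_boot_scores")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 patients")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  set.seed(seed)
  aucs <- numeric(n_iter)
  if (method == "loo_boot_scores") {
    sc <- loo_scores(X, y)
    for (b in seq_len(n_iter)) {
      idx <- resample_both_classes(n, y)
      aucs[b] <- compute_auc(sc[idx], y[idx])
    }
  } else {
    for (b in seq_len(n_iter)) {
      idx <- resample_both_classes(n, y)
      u <- sort(unique(idx))
      sc <- numeric(length(u))
      ok <- TRUE
      for (i in seq_along(u)) {
        tr <- idx[idx != u[i]]
        if (length(unique(y[tr])) < 2L) { sc[i] <- NA_real_; next }
        fit <- fit_logistic(X[tr, , drop = FALSE], y[tr])
        sc[i] <- predict_logistic(fit, X[u[i], , drop = FALSE])
      }
      val <- !is.na(sc)
      if (sum(val) < 2L || length(unique(y[u[val]])) < 2L) {
        aucs[b] <- NA_real_
      } else {
        aucs[b] <- compute_auc(sc[val], y[u[val]])
      }
    }
  }
  aucs_ok <- aucs[!is.na(aucs)]
  if (length(aucs_ok) == 0) stop("no evaluable bootstrap iteration")
  list(auc = aucs, median = stats::median(aucs_ok),
       ci = stats::quantile(aucs_ok, c(0.025, 0.975), names = FALSE))
}

resample_both_classes <- function(n, y, max_tries = 100L) {
  for (t in seq_len(max_tries)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) == 2L) return(idx)
  }
  stop("bootstrap resample lacked both classes after ", max_tries, " redraws")
}

loo_scores <- function(X, y) {
  n <- nrow(X)
  sc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y[tr])) < 2L) next
    fit <- fit_logistic(X[tr, , drop = FALSE], y[tr])
    sc[i] <- predict_logistic(fit, X[i, , drop = FALSE])
  }
  sc
}

#' ROC points from scores
#' @param scores numeric predictions.
#' @param labels binary labels.
#' @return data.frame with `fpr`, `tpr` sorted by decreasing threshold.
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  labels <- as.integer(labels)[ord]
  tpr <- c(0, cumsum(labels == 1) / max(1, sum(labels == 1)))
  fpr <- c(0, cumsum(labels == 0) / max(1, sum(labels == 0)))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Fit and validate per-bin logistic models for one endpoint
#'
#' Runs the full modeling stage: pooled random-forest ranking, correlation
#' filtering, top-7 selection, then one logistic model per BED bin with a
#' bootstrap-LOO AUC distribution and an ROC from the all-data LOO pass.
#'
#' @param drf_array 3D array patients x bins x features (dimnames required).
#' @param labels matrix patients x bins of 0/1 endpoint labels (constant
#'   columns for bin-invariant endpoints).
#' @param extra_covariates optional patients x k matrix of always-candidate
#'   clinical covariates (e.g. baseline IPSS), exempt from the correlation
#'   filter.
#' @param n_trees,features_per_split,bag_fraction forest parameters.
#' @param cor_threshold correlation-filter threshold (default 0.8).
#' @param max_features selection cap (default 7).
#' @param n_iter bootstrap iterations per bin (default 1000).
#' @param seed RNG seed for selection and validation.
#' @param method bootstrap flavor, see [loo_bootstrap_auc()].
#' @param eval_bins bins to validate (names like "BED20"); others are fit
#'   but not bootstrapped. Default: all. Each bin has its own RNG stream,
#'   so restricting this never changes another bin's results.
#' @return object of class `drf_models`: selection details plus one entry
#'   per bin with coefficients, AUC distribution summary and ROC points.
#' @export
fit_endpoint_models <- function(drf_array, labels, extra_covariates = NULL,
                                n_trees = 500L, features_per_split = 7L,
                                bag_fraction = 2 / 3, cor_threshold = 0.8,
                                max_features = 7L, n_iter = 1000L, seed = 1L,
                                method = "bootstrap_loo", eval_bins = NULL) {
  dn <- dimnames(drf_array)
  patients <- dn[[1]]; bins <- dn[[2]]; feats <- dn[[3]]
  exempt <- character(0)

  # Pool rows (patient x bin) for selection, each with its own bin's label.
  # Features are standardized within each bin before pooling: DRF magnitudes
  # grow with accumulated BED, and that bin-level variance would otherwise
  # swamp the within-bin class signal the ranking is supposed to find. The
  # per-bin models below always use raw DRFs.
  rows <- list(); ys <- integer(0)
  for (b in seq_along(bins)) {
    Xb <- drf_array[, b, , drop = TRUE]
    if (is.null(dim(Xb))) Xb <- matrix(Xb, nrow = 1, dimnames = list(patients, feats))
    ok <- stats::complete.cases(Xb)
    if (!any(ok)) next
    Xb <- Xb[ok, , drop = FALSE]
    if (!is.null(extra_covariates))
      Xb <- cbind(Xb, extra_covariates[ok, , drop = FALSE])
    Xb <- apply(Xb, 2, function(v) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    if (is.null(dim(Xb))) Xb <- matrix(Xb, nrow = 1)
    rows[[length(rows) + 1L]] <- Xb
    ys <- c(ys, labels[ok, b])
  }
  Xpool <- do.call(rbind, rows)
  # drop features that are NA (flagged baseline) or constant in the pool
  keep_col <- apply(Xpool, 2, function(v) all(is.finite(v)) && stats::sd(v) > 0)
  if (!is.null(extra_covariates)) {
    exempt <- colnames(extra_covariates)
    keep_col[exempt] <- apply(Xpool[, exempt, drop = FALSE], 2,
                              function(v) all(is.finite(v)))
  }
  Xpool <- Xpool[, keep_col, drop = FALSE]

  ranking <- rf_gini_importance(Xpool, ys, n_trees = n_trees,
                                features_per_split = features_per_split,
                                bag_fraction = bag_fraction, seed = seed)
  filtered <- correlation_filter(Xpool, ranking, threshold = cor_threshold,
                                 exempt = exempt)
  selected <- select_features(filtered, max_features)

  per_bin <- vector("list", length(bins))
  names(per_bin) <- bins
  for (b in seq_along(bins)) {
    Xb <- drf_array[, b, , drop = TRUE]
    if (is.null(dim(Xb))) Xb <- matrix(Xb, nrow = 1, dimnames = list(patients, feats))
    if (!is.null(extra_covariates)) Xb <- cbind(Xb, extra_covariates)
    sel_here <- intersect(selected, colnames(Xb))
    Xb <- Xb[, sel_here, drop = FALSE]
    ok <- stats::complete.cases(Xb)
    Xb <- Xb[ok, , drop = FALSE]
    yb <- labels[ok, b]
    if (nrow(Xb) < 4L || length(unique(yb)) < 2L) {
      per_bin[[b]] <- list(evaluable = FALSE, n = nrow(Xb))
      next
    }
    fit <- fit_logistic(Xb, yb)
    if (!is.null(eval_bins) && !(bins[b] %in% eval_bins)) {
      per_bin[[b]] <- list(evaluable = FALSE, n = nrow(Xb),
                           coefficients = fit$coefficients, skipped = TRUE)
      next
    }
    boot <- tryCatch(
      loo_bootstrap_auc(Xb, yb, n_iter = n_iter,
                        seed = seed + 7L * b, method = method),
      error = function(e) NULL)
    if (is.null(boot)) {  # e.g. minority class too small to validate
      per_bin[[b]] <- list(evaluable = FALSE, n = nrow(Xb))
      next
    }
    sc <- loo_scores(Xb, yb)
    val <- !is.na(sc)
    roc <- if (any(val)) roc_points(sc[val], yb[val]) else NULL
    per_bin[[b]] <- list(evaluable = TRUE, n = nrow(Xb),
                         coefficients = fit$coefficients,
                         ridge_used = fit$ridge_used,
                         auc = boot$auc, auc_median = boot$median,
                         auc_ci = boot$ci, roc = roc)
  }
  structure(list(selected_features = selected, ranking = ranking,
                 filtered = filtered, bins = bins, per_bin = per_bin,
                 seed = seed),
            class = "drf_models")
}

#' @export
print.drf_models <- function(x, ...) {
  cat("<drf_models> features:", paste(x$selected_features, collapse = ", "),
      "\n")
  for (b in names(x$per_bin)) {
    pb <- x$per_bin[[b]]
    if (isTRUE(pb$evaluable)) {
      cat(sprintf("  %-7s n=%-3d median AUC %.3f (%.3f-%.3f)\n", b, pb$n,
                  pb$auc_median, pb$auc_ci[1], pb$auc_ci[2]))
    } else {
      cat(sprintf("  %-7s unevaluable (n=%d or single class)\n", b, pb$n))
    }
  }
  invisible(x)
}
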