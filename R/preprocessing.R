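## Preprocessing of the prostate ROI ahead of feature extraction:
## gold-fiducial streak-artifact removal, Collewet 3-sigma re-segmentation,
## and gray-level quantization (uniform or Lloyd-Max). Standard deviations
## throughout use the population (n) denominator, the re-segmentation
## convention of the IBSI RS:3sigma rule.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Remove gold-fiducial streak artifacts from an ROI mask
#'
#' Axial layers (z slices) intersecting a fiducial's physical extent are
#' treated as artifact layers. An intensity acceptance range
#' `[mu_AL - 3 sigma_AL, mu_AL + 3 sigma_AL]` is estimated from ROI voxels on
#' the remaining layers. On artifact layers, ROI voxels inside a circle of
#' `radius_mm` around each fiducial whose intensity falls outside the range
#' are removed, and — to catch radial streak spokes — every such
#' above-threshold pixel seeds a rasterized line mask back to the fiducial
#' center whose in-ROI pixels are removed as well. Voxels on non-artifact
#' layers are never touched.
#'
#' @param vol an [image_volume()].
#' @param mask an [roi_mask()] aligned with `vol`.
#' @param fiducial_centers_mm matrix/data.frame with columns x, y, z in mm
#'   (volume-corner origin), one row per fiducial; may have zero rows.
#' @param radius_mm in-plane removal radius around each fiducial (default 5).
#' @param fiducial_halflength_mm half-length of the fiducial along z used to
#'   decide which layers it contaminates (default 2.5, a 5 mm gold marker).
#' @return list with `cleaned_mask`, `removed_fraction`, `threshold_range`,
#'   `artifact_layers`, `mu_al`, `sigma_al`.
#' @export
remove_fiducial_artifacts <- function(vol, mask, fiducial_centers_mm,
                                      radius_mm = 5.0,
                                      fiducial_halflength_mm = 2.5) {
  check_alignment(vol, mask)
  ctr <- fiducial_centers_mm
  if (is.null(ctr) || NROW(ctr) == 0L) {
    return(list(cleaned_mask = mask, removed_fraction = 0,
                threshold_range = c(NA_real_, NA_real_),
                artifact_layers = integer(0),
                mu_al = NA_real_, sigma_al = NA_real_))
  }
  ctr <- as.matrix(ctr)[, 1:3, drop = FALSE]
  d <- dim(vol$values)
  sp <- vol$spacing_mm
  zc <- (seq_len(d[3]) - 0.5) * sp[3]
  art_layer <- vapply(zc, function(z)
    any(abs(z - ctr[, 3]) <= fiducial_halflength_mm), logical(1))
  if (all(art_layer))
    stop("every axial layer intersects a fiducial; ",
         "artifact threshold is undefined")
  clean_vals <- vol$values[, , !art_layer, drop = FALSE]
  clean_msk <- mask$values[, , !art_layer, drop = FALSE]
  ref <- clean_vals[clean_msk]
  if (length(ref) < 2L)
    stop("no ROI voxels on artifact-free layers; threshold undefined")
  mu <- mean(ref)
  sg <- pop_sd(ref)
  lo <- mu - 3 * sg
  hi <- mu + 3 * sg

  xc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  out <- mask$values
  for (k in which(art_layer)) {
    sl_mask <- mask$values[, , k]
    if (!any(sl_mask)) next
    sl_val <- vol$values[, , k]
    remove2d <- matrix(FALSE, d[1], d[2])
    for (f in seq_len(nrow(ctr))) {
      if (abs(zc[k] - ctr[f, 3]) > fiducial_halflength_mm) next
      dx <- outer(xc - ctr[f, 1], rep(1, d[2]))
      dy <- outer(rep(1, d[1]), yc - ctr[f, 2])
      in_circle <- (dx^2 + dy^2) <= radius_mm^2
      bad <- in_circle & sl_mask & (sl_val < lo | sl_val > hi)
      remove2d <- remove2d | bad
      if (any(bad)) {
        ci <- max(1L, min(d[1], as.integer(ceiling(ctr[f, 1] / sp[1]))))
        cj <- max(1L, min(d[2], as.integer(ceiling(ctr[f, 2] / sp[2]))))
        w <- which(bad, arr.ind = TRUE)
        for (r in seq_len(nrow(w))) {
          ln <- raster_line_2d(w[r, 1], w[r, 2], ci, cj)
          remove2d[ln] <- TRUE
        }
      }
    }
    out[, , k] <- sl_mask & !remove2d
  }
  n0 <- sum(mask$values)
  cleaned <- roi_mask(out, mask$spacing_mm)
  list(cleaned_mask = cleaned,
       removed_fraction = (n0 - sum(out)) / n0,
       threshold_range = c(lo, hi),
       artifact_layers = which(art_layer),
       mu_al = mu, sigma_al = sg)
}

## Bresenham-style 2D integer line between (x0,y0) and (x1,y1); returns an
## index matrix usable for matrix subsetting. No rasterization rule is
## canonical for streak masks, so the classic integer midpoint walk is used.
raster_line_2d <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  xs <- integer(dx + dy + 1L); ys <- integer(dx + dy + 1L)
  i <- 0L
  repeat {
    i <- i + 1L
    xs[i] <- x0; ys[i] <- y0
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; y0 <- y0 + sy }
  }
  cbind(xs[seq_len(i)], ys[seq_len(i)])
}

#' Collewet 3-sigma re-segmentation
#'
#' Restricts the ROI to voxels whose intensity lies in the closed range
#' `[mu_R - 3 sigma_R, mu_R + 3 sigma_R]`, with `mu_R`/`sigma_R` the mean and
#' population standard deviation of the input-ROI intensities. A constant ROI
#' (`sigma_R = 0`) is returned unchanged. Not idempotent in general: removing
#' voxels changes the statistics of a second pass.
#'
#' @inheritParams remove_fiducial_artifacts
#' @return an [roi_mask()], subset of the input mask.
#' @export
collewet_resegment <- function(vol, mask) {
  check_alignment(vol, mask)
  if (mask_voxel_count(mask) < 2L)
    stop("re-segmentation needs at least 2 ROI voxels")
  v <- vol$values[mask$values]
  mu <- mean(v)
  sg <- pop_sd(v)
  if (sg == 0) return(mask)
  keep <- mask$values & vol$values >= (mu - 3 * sg) &
    vol$values <= (mu + 3 * sg)
  roi_mask(keep, mask$spacing_mm)
}

new_quantized_roi <- function(levels, n_levels, quantizer, spacing_mm,
                              mu_r, sigma_r, reps, mse,
                              collewet_applied = FALSE) {
  structure(list(levels = levels, n_levels = n_levels, quantizer = quantizer,
                 spacing_mm = spacing_mm, collewet_applied = collewet_applied,
                 source_stats = c(mu = mu_r, sigma = sigma_r),
                 representatives = reps, mse = mse),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat("<quantized_roi> ", x$quantizer, " quantizer, G=", x$n_levels,
      ", ", sum(x$levels > 0), " voxels, MSE=", format(x$mse, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Uniform (fixed-bin-number) gray-level quantization of an ROI
#'
#' Bins are distributed evenly from the lowest to the highest in-ROI gray
#' level: `level = min(G, floor(G * (v - min) / (max - min)) + 1)`, half-open
#' bins with the top bin closed, so the minimum maps to 1 and the maximum to
#' G. A constant ROI maps to level 1. The reported quantization MSE uses the
#' conditional mean of each occupied bin as its reconstruction level, which
#' makes it directly comparable with [quantize_lloyd_max()].
#'
#' @inheritParams remove_fiducial_artifacts
#' @param n_levels number of gray levels G (default 256).
#' @param collewet_applied provenance flag stored on the result.
#' @return a `quantized_roi` object.
#' @export
quantize_uniform <- function(vol, mask, n_levels = 256L,
                             collewet_applied = FALSE) {
  check_alignment(vol, mask)
  if (mask_voxel_count(mask) < 1L) stop("empty mask")
  G <- as.integer(n_levels)
  v <- vol$values[mask$values]
  rng <- max(v) - min(v)
  if (rng == 0) {
    lv <- rep(1L, length(v))
  } else {
    lv <- pmin(G, floor(G * (v - min(v)) / rng) + 1L)
  }
  levels <- array(0L, dim(vol$values))
  levels[mask$values] <- as.integer(lv)
  cnt <- tabulate(lv, nbins = G)
  sums <- numeric(G)
  rs <- rowsum(v, lv)
  sums[as.integer(rownames(rs))] <- rs
  reps <- ifelse(cnt > 0, sums / cnt, NA_real_)
  mse <- mean((v - reps[lv])^2)
  new_quantized_roi(levels, G, "uniform", vol$spacing_mm,
                    mean(v), pop_sd(v), reps, mse, collewet_applied)
}

#' Lloyd-Max (minimum-MSE) gray-level quantization of an ROI
#'
#' Lloyd iteration on the empirical in-ROI intensity distribution: decision
#' boundaries are midpoints of adjacent representative levels, representative
#' levels are conditional means within boundaries. Initialization uses the
#' uniform-quantizer partition (deterministic, no random restarts), so the
#' resulting MSE can never exceed that of [quantize_uniform()] with the same
#' G. If the ROI has no more distinct values than levels, each distinct value
#' gets its own level and the MSE is exactly 0.
#'
#' @inheritParams quantize_uniform
#' @param tol stop when the MSE improves by less than this (default 1e-7).
#' @param max_iter iteration cap (default 500).
#' @return a `quantized_roi` object.
#' @export
quantize_lloyd_max <- function(vol, mask, n_levels = 256L, tol = 1e-7,
                               max_iter = 500L, collewet_applied = FALSE) {
  check_alignment(vol, mask)
  if (mask_voxel_count(mask) < 1L) stop("empty mask")
  G <- as.integer(n_levels)
  v <- vol$values[mask$values]
  ux <- sort(unique(v))

  if (length(ux) <= G) {
    lv <- match(v, ux)
    reps <- c(ux, rep(NA_real_, G - length(ux)))
    mse <- 0
  } else {
    x <- sort(v)
    n <- length(x)
    cs <- cumsum(x)
    cs2 <- cumsum(x^2)
    seg_sum <- function(a, b) if (b < a) 0 else cs[b] - if (a > 1) cs[a - 1] else 0
    seg_sum2 <- function(a, b) if (b < a) 0 else cs2[b] - if (a > 1) cs2[a - 1] else 0

    # initial partition = uniform quantizer bins
    rng <- x[n] - x[1]
    lv0 <- pmin(G, floor(G * (x - x[1]) / rng) + 1L)
    hi_idx <- cumsum(tabulate(lv0, nbins = G))   # last sorted index per bin
    reps <- numeric(G)
    prev <- 0
    for (g in seq_len(G)) {
      hi <- hi_idx[g]
      reps[g] <- if (hi > prev) seg_sum(prev + 1, hi) / (hi - prev)
      else x[1] + (g - 0.5) * rng / G           # empty bin: keep center
      prev <- hi
    }
    mse_of <- function(hi_idx, reps) {
      prev <- 0; acc <- 0
      for (g in seq_len(G)) {
        hi <- hi_idx[g]
        if (hi > prev)
          acc <- acc + seg_sum2(prev + 1, hi) -
            2 * reps[g] * seg_sum(prev + 1, hi) + (hi - prev) * reps[g]^2
        prev <- hi
      }
      acc / n
    }
    mse <- mse_of(hi_idx, reps)
    for (it in seq_len(max_iter)) {
      b <- (reps[-G] + reps[-1]) / 2
      hi_idx <- c(findInterval(b, x), n)
      hi_idx <- cummax(hi_idx)                   # guard against disorder
      prev <- 0
      for (g in seq_len(G)) {
        hi <- hi_idx[g]
        if (hi > prev) reps[g] <- seg_sum(prev + 1, hi) / (hi - prev)
        prev <- hi
      }
      new_mse <- mse_of(hi_idx, reps)
      if (mse - new_mse < tol) { mse <- min(mse, new_mse); break }
      mse <- new_mse
    }
    b <- (reps[-G] + reps[-1]) / 2
    lv <- findInterval(v, b) + 1L
  }
  levels <- array(0L, dim(vol$values))
  levels[mask$values] <- as.integer(lv)
  new_quantized_roi(levels, G, "lloyd_max", vol$spacing_mm,
                    mean(v), pop_sd(v), reps, mse, collewet_applied)
}

#' Quantization mean-squared error of a `quantized_roi`
#' @param q a `quantized_roi`.
#' @export
quantization_mse <- function(q) q$mse
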