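## Delta-feature computation and biologically-effective-dose (BED) binning.
## The BED of a schedule of n fractions at d Gy/fraction is
## n * d * (1 + d / (alpha/beta)), with alpha/beta = 3 Gy for prostate, and
## the per-fraction feature change is normalized to the first fraction:
## DRF = (RF_N - RF_1) / |RF_1|. DRFs are averaged inside 20 Gy bins of
## accumulated BED from 20 to 120 Gy, aligning mixed fractionation schedules
## on one biological time axis (one bin is roughly a week of treatment).

#' Dose-fractionation schedule
#'
#' @param n_fractions number of fractions (>= 1).
#' @param dose_per_fraction dose per fraction in Gy; alternatively give
#'   `total_dose` and it is derived as `total_dose / n_fractions`.
#' @param total_dose optional total physical dose in Gy.
#' @param alpha_beta linear-quadratic alpha/beta ratio in Gy (default 3,
#'   prostate).
#' @return an object of class `schedule`.
#' @export
schedule <- function(n_fractions, dose_per_fraction = NULL, total_dose = NULL,
                     alpha_beta = 3) {
  if (is.null(dose_per_fraction)) {
    if (is.null(total_dose)) stop("give dose_per_fraction or total_dose")
    dose_per_fraction <- total_dose / n_fractions
  }
  if (n_fractions < 1 || dose_per_fraction <= 0)
    stop("need n_fractions >= 1 and dose_per_fraction > 0")
  if (alpha_beta <= 0) stop("alpha/beta must be positive")
  structure(list(n = as.integer(n_fractions), d = dose_per_fraction,
                 alpha_beta = alpha_beta),
            class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat("<schedule> ", x$n, " x ", format(x$d), " Gy (",
      format(x$n * x$d), " Gy total), BED ",
      format(compute_bed(x), digits = 5), " Gy at a/b=", x$alpha_beta,
      "\n", sep = "")
  invisible(x)
}

#' Biologically effective dose of a full schedule
#' @param sched a [schedule()].
#' @return BED in Gy: `n * d * (1 + d / alpha_beta)`.
#' @export
compute_bed <- function(sched) cumulative_bed(sched, sched$n)

#' Accumulated BED after k delivered fractions
#' @param sched a [schedule()].
#' @param k fractions delivered, `0 <= k <= n`.
#' @export
cumulative_bed <- function(sched, k) {
  if (any(k < 0) || any(k > sched$n)) stop("k out of range 0..n")
  k * sched$d * (1 + sched$d / sched$alpha_beta)
}

#' Delta-radiomic feature: relative change versus the first fraction
#'
#' `DRF = (rf_n - rf_1) / |rf_1|`; the absolute value in the denominator
#' preserves the sign of the change for negative baselines. Baselines with
#' `|rf_1| < eps` produce an untrustworthy ratio; use [drf_baseline_flag()]
#' to detect and drop them.
#'
#' @param rf_n feature value at fraction N.
#' @param rf_1 feature value at fraction 1.
#' @param eps guard on the denominator (default 1e-12).
#' @export
compute_drf <- function(rf_n, rf_1, eps = 1e-12) {
  (rf_n - rf_1) / pmax(abs(rf_1), eps)
}

#' Flag near-zero DRF baselines
#' @inheritParams compute_drf
#' @export
drf_baseline_flag <- function(rf_1, eps = 1e-12) abs(rf_1) < eps

#' The standard 20 Gy BED bin uppers, 20..120 Gy
#' @export
bed_bins <- function() seq(20, 120, by = 20)

#' Assign delivered fractions to BED bins
#'
#' Fraction k belongs to bin b iff its accumulated BED lies in `(b - 20, b]`
#' (half-open, upper edge included). Fractions beyond 120 Gy accumulated BED
#' are dropped.
#'
#' @param sched a [schedule()].
#' @param bins bin uppers (default [bed_bins()]).
#' @return integer vector length `n`: bin upper in Gy per fraction, NA when
#'   beyond the last bin.
#' @export
assign_bins <- function(sched, bins = bed_bins()) {
  cb <- cumulative_bed(sched, seq_len(sched$n))
  width <- diff(c(0, bins))[1]
  idx <- ceiling(cb / width - 1e-9)
  out <- bins[idx]
  out[idx > length(bins)] <- NA_integer_
  out
}

#' Average per-fraction delta features inside BED bins
#'
#' Converts a fractions-by-features matrix of raw feature values into a
#' bins-by-features matrix of averaged DRFs. Fraction 1 (whose DRF is
#' identically 0) is included in the first bin's average by default.
#' Features whose fraction-1 baseline is below `eps` in absolute value are
#' flagged and set to NA for this patient rather than producing huge ratios.
#'
#' @param per_fraction_features numeric matrix, one row per fraction 1..n,
#'   columns named by feature.
#' @param sched the [schedule()] the fractions follow.
#' @param bins bin uppers (default [bed_bins()]).
#' @param include_first include fraction 1 in the first bin (default TRUE).
#' @param eps near-zero baseline guard.
#' @return list with `values` (bins x features), `missing` (logical per
#'   bin: no fraction landed there), `flagged` (character: dropped
#'   features), `bin_of_fraction`.
#' @export
bin_drfs <- function(per_fraction_features, sched, bins = bed_bins(),
                     include_first = TRUE, eps = 1e-12) {
  X <- as.matrix(per_fraction_features)
  if (nrow(X) != sched$n)
    stop("need one feature row per fraction (got ", nrow(X), ", schedule ",
         sched$n, ")")
  bin_of <- assign_bins(sched, bins)
  if (all(is.na(bin_of))) stop("schedule too short: no fraction in any bin")
  rf1 <- X[1, ]
  flagged <- colnames(X)[drf_baseline_flag(rf1, eps)]
  D <- compute_drf(X, matrix(rf1, nrow(X), ncol(X), byrow = TRUE), eps)
  D[, colnames(X) %in% flagged] <- NA_real_
  use <- !is.na(bin_of)
  if (!include_first) use[1] <- FALSE
  vals <- matrix(NA_real_, length(bins), ncol(X),
                 dimnames = list(paste0("BED", bins), colnames(X)))
  missing <- rep(TRUE, length(bins))
  for (b in seq_along(bins)) {
    rows <- which(use & bin_of == bins[b])
    if (length(rows) > 0) {
      vals[b, ] <- colMeans(D[rows, , drop = FALSE])
      missing[b] <- FALSE
    }
  }
  list(values = vals, missing = missing, flagged = flagged,
       bin_of_fraction = bin_of)
}
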