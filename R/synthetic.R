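## Seeded phantom-cohort generator. Real daily CBCT of the prostate is not
## publicly available, so every downstream stage is exercised on synthetic
## fractionated image series with the statistical structure the analysis
## assumes: an ellipsoidal prostate-like ROI filled with speckle texture
## whose contrast rises and autocorrelation length falls fraction by
## fraction at a per-patient drift rate; bright gold-fiducial rods with
## radial streak spokes; binary toxicity outcomes and IPSS changes coupled
## to the drift rate. Two drift-rate distributions, separated by
## `texture_effect_size` (in units of the drift SD), generate the outcome
## classes; with effect 0 the labels are independent of the images.
##
## The textured field is soft-clipped (2.5 * tanh(x / 2.5)) as the last step
## before fiducial injection, so in the absence of fiducials no ROI voxel
## can exceed the mean by 3 standard deviations — this makes the 3-sigma
## artifact threshold provably separate fiducial voxels (injected at
## mean + 8 SD) from tissue texture.

#' Configuration of a synthetic phantom cohort
#'
#' @param n_patients number of patients (>= 2).
#' @param schedules list of `c(total_dose_gy, n_fractions)` pairs; patients
#'   are assigned schedules with probabilities `schedule_probs`.
#' @param schedule_probs assignment probabilities (default `c(0.75, 0.25)`
#'   for two schedules, mirroring a conventional 3:1 mix of standard and
#'   moderately hypofractionated courses; uniform otherwise).
#' @param grid_shape voxels per axis (default `c(64, 64, 32)`).
#' @param voxel_spacing_mm voxel spacing (default `c(0.9, 0.9, 2)` mm,
#'   the in-plane pixel size and slice thickness of daily CBCT).
#' @param n_fiducials gold fiducial markers per patient (default 3).
#' @param texture_effect_size separation of the two drift-rate
#'   distributions in drift-SD units (default 1.5; 3 is the documented
#'   "strong" setting, 0 removes any image-outcome association).
#' @param outcome_prevalence probability of the toxicity class, in (0, 1).
#' @param noise_style `"sharp"` (filtered-backprojection-like speckle) or
#'   `"smooth"` (an extra low-pass emulating iterative reconstruction).
#' @param seed master RNG seed; identical (config, seed) pairs reproduce
#'   bit-identical cohorts.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20L,
                          schedules = list(c(80, 40), c(70.2, 26)),
                          schedule_probs = NULL,
                          grid_shape = c(64L, 64L, 32L),
                          voxel_spacing_mm = c(0.9, 0.9, 2.0),
                          n_fiducials = 3L,
                          texture_effect_size = 1.5,
                          outcome_prevalence = 0.5,
                          noise_style = c("sharp", "smooth"),
                          seed = 1L) {
  noise_style <- match.arg(noise_style)
  if (n_patients < 2L) stop("configuration error: n_patients must be >= 2")
  for (s in schedules)
    if (length(s) != 2L || s[2] < 2L)
      stop("configuration error: each schedule needs (total_dose, n >= 2)")
  if (!is.finite(outcome_prevalence) || outcome_prevalence <= 0 ||
      outcome_prevalence >= 1)
    stop("configuration error: prevalence must be in (0, 1)")
  if (!is.finite(texture_effect_size) || texture_effect_size < 0)
    stop("configuration error: texture_effect_size must be >= 0")
  if (is.null(schedule_probs)) {
    schedule_probs <- if (length(schedules) == 2L) c(0.75, 0.25)
    else rep(1 / length(schedules), length(schedules))
  }
  structure(list(
    n_patients = as.integer(n_patients), schedules = schedules,
    schedule_probs = schedule_probs / sum(schedule_probs),
    grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    n_fiducials = as.integer(n_fiducials),
    texture_effect_size = texture_effect_size,
    outcome_prevalence = outcome_prevalence,
    noise_style = noise_style, seed = as.integer(seed)
  ), class = "cohort_config")
}

## Generator world constants (see the methods vignette for rationale).
synth_defaults <- function() {
  list(base_level = 100, contrast0 = 20, corr_len0_mm = 4, noise_sd = 5,
       smooth_sigma_mm = 1.5, clip = 2.5,
       drift_mu0 = 0.010, drift_sd = 0.005,
       roi_semiaxes_mm = c(20, 20, 24),   # ~40 cc ellipsoid at full scale
       rod_radius_mm = 1.0, rod_halflength_mm = 2.5,
       spoke_length_mm = 6.0, n_spokes = 4L)
}

#' The documented "strong" texture effect size
#' @export
texture_effect_strong <- function() 3.0

patient_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * i) %% 2147483647)
}

## Latent draws only (no images): drift rates and outcome classes. Used for
## population-level association properties without paying for volumes.
cohort_latents <- function(config) {
  df <- synth_defaults()
  n <- config$n_patients
  drift <- numeric(n); outcome <- integer(n); sched_i <- integer(n)
  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    outcome[i] <- stats::rbinom(1, 1, config$outcome_prevalence)
    mu <- df$drift_mu0 + config$texture_effect_size * df$drift_sd * outcome[i]
    drift[i] <- max(0, stats::rnorm(1, mu, df$drift_sd))
    sched_i[i] <- sample.int(length(config$schedules), 1,
                             prob = config$schedule_probs)
  }
  data.frame(patient = seq_len(n), drift_rate = drift, outcome = outcome,
             schedule_index = sched_i)
}

#' Generate a synthetic phantom cohort
#'
#' Draws per-patient latent state (schedule, drift rate, outcome class,
#' fiducial geometry, toxicity events, IPSS scores) from independent
#' per-patient RNG streams derived from the master seed, so the cohort is a
#' pure function of (config, seed) and any patient can be regenerated in
#' isolation. Image volumes are generated on demand by
#' [generate_phantom_fraction()]; set `materialize = TRUE` to attach all
#' fraction volumes (only sensible for small cohorts/grids).
#'
#' @param config a [cohort_config()].
#' @param materialize attach all fraction volumes to each patient.
#' @return list of `synthetic_patient` objects.
#' @export
generate_cohort <- function(config, materialize = FALSE) {
  if (!inherits(config, "cohort_config")) stop("need a cohort_config")
  df <- synth_defaults()
  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pseed <- patient_seed(config$seed, i)
    set.seed(pseed)
    outcome <- stats::rbinom(1, 1, config$outcome_prevalence)
    mu <- df$drift_mu0 + config$texture_effect_size * df$drift_sd * outcome
    drift <- max(0, stats::rnorm(1, mu, df$drift_sd))
    si <- sample.int(length(config$schedules), 1,
                     prob = config$schedule_probs)
    sc <- config$schedules[[si]]
    sched <- schedule(n_fractions = sc[2], total_dose = sc[1])
    total_bed <- compute_bed(sched)

    geom <- roi_geometry(config)
    fid <- draw_fiducials(config, geom, df)

    ev <- draw_events(outcome, total_bed)
    ipss_i <- sample(3:25, 1)
    delta <- round(stats::rnorm(1, mean = 5 * outcome - 2.5, sd = 3))
    ipss_f <- min(35L, max(0L, ipss_i + delta))

    patients[[i]] <- structure(list(
      patient_id = sprintf("P%03d", i), seed = pseed, schedule = sched,
      drift_rate = drift, outcome = outcome,
      toxicity_events = ev, ipss_initial = ipss_i, ipss_final = ipss_f,
      grid_shape = config$grid_shape,
      voxel_spacing_mm = config$voxel_spacing_mm,
      noise_style = config$noise_style,
      roi_center_mm = geom$center, roi_semiaxes_mm = geom$semiaxes,
      fiducial_centers_mm = fid$centers, spoke_angles = fid$angles
    ), class = "synthetic_patient")
    if (materialize) {
      patients[[i]]$fractions <- lapply(seq_len(sched$n), function(k)
        generate_phantom_fraction(patients[[i]], k))
    }
  }
  patients
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat("<synthetic_patient> ", x$patient_id, ": ", x$schedule$n, " fx, drift ",
      format(x$drift_rate, digits = 3), ", outcome ", x$outcome,
      ", IPSS ", x$ipss_initial, "->", x$ipss_final, "\n", sep = "")
  invisible(x)
}

roi_geometry <- function(config) {
  df <- synth_defaults()
  extent <- config$grid_shape * config$voxel_spacing_mm
  ax <- df$roi_semiaxes_mm
  scale <- min(1, min(0.425 * extent / ax))
  list(center = extent / 2, semiaxes = ax * scale)
}

draw_fiducials <- function(config, geom, df) {
  nf <- config$n_fiducials
  if (nf == 0L)
    return(list(centers = matrix(numeric(0), 0, 3,
                                 dimnames = list(NULL, c("x", "y", "z"))),
                angles = list()))
  centers <- matrix(0, nf, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (f in seq_len(nf)) {
    repeat {  # uniform inside half-scale ellipsoid
      u <- stats::runif(3, -0.5, 0.5)
      if (sum(u^2 / 0.25) <= 1) break
    }
    centers[f, ] <- geom$center + u * geom$semiaxes
  }
  angles <- lapply(seq_len(nf), function(f)
    stats::runif(df$n_spokes, 0, 2 * pi))
  list(centers = centers, angles = angles)
}

draw_events <- function(outcome, total_bed) {
  ev <- toxicity_events()
  if (outcome == 1L) {
    ev <- rbind(ev, toxicity_events(
      grade = sample(2:3, 1), onset_bed = stats::runif(1, 0, total_bed),
      phase = "during_RT", symptom = sample(gu_symptoms, 1)))
    if (stats::runif(1) < 0.6)
      ev <- rbind(ev, toxicity_events(
        grade = sample(2:3, 1), onset_bed = total_bed,
        phase = "post_RT", symptom = sample(gu_symptoms, 1)))
    if (stats::runif(1) < 0.4)
      ev <- rbind(ev, toxicity_events(
        grade = 1L, onset_bed = stats::runif(1, 0, total_bed),
        phase = "during_RT", symptom = sample(gu_symptoms, 1)))
  } else {
    if (stats::runif(1) < 0.3)
      ev <- rbind(ev, toxicity_events(
        grade = 1L, onset_bed = stats::runif(1, 0, total_bed),
        phase = "during_RT", symptom = sample(gu_symptoms, 1)))
    if (stats::runif(1) < 0.2)
      ev <- rbind(ev, toxicity_events(
        grade = 1L, onset_bed = total_bed,
        phase = "post_RT", symptom = sample(gu_symptoms, 1)))
  }
  ev
}

## FFT-based separable Gaussian smoothing (periodic boundaries; the field is
## statistically homogeneous so wraparound is harmless).
gaussian_smooth_fft <- function(arr, sigma_vox) {
  d <- dim(arr)
  H <- 1
  for (a in 1:3) {
    n <- d[a]
    k <- c(0:floor(n / 2), -((ceiling(n / 2) - 1):1)) / n
    if (n == 1) k <- 0
    h1 <- exp(-2 * pi^2 * sigma_vox[a]^2 * k^2)
    shape <- c(1, 1, 1); shape[a] <- n
    H <- H * array(rep(h1, each = prod(d[seq_len(a - 1)])), dim = d)
  }
  Re(stats::fft(stats::fft(arr) * H, inverse = TRUE)) / prod(d)
}

#' Generate one phantom fraction image
#'
#' Deterministic given (patient, fraction_index): the per-fraction RNG
#' stream is derived from the patient seed and the fraction index. The
#' speckle contrast grows and the autocorrelation length shrinks with the
#' fraction index at the patient's drift rate; fiducial rods are injected at
#' ROI mean + 8 SD with streak spokes at + 7 SD, and the ground-truth
#' artifact voxels are returned for validation.
#'
#' @param patient a `synthetic_patient` (see [generate_cohort()]).
#' @param fraction_index fraction number, 1-based.
#' @return list with `volume` ([image_volume()]), `mask` ([roi_mask()]),
#'   `fiducial_centers_mm`, and `artifact_voxels` (index matrix of injected
#'   artifact voxels).
#' @export
generate_phantom_fraction <- function(patient, fraction_index) {
  if (fraction_index < 1) stop("fraction_index must be >= 1")
  df <- synth_defaults()
  d <- patient$grid_shape
  sp <- patient$voxel_spacing_mm
  geom <- list(center = patient$roi_center_mm,
               semiaxes = patient$roi_semiaxes_mm)
  if (any(2 * geom$semiaxes > d * sp))
    stop("configuration error: ROI larger than grid")
  set.seed(as.integer((patient$seed + 7919 * fraction_index) %% 2147483647))

  g <- 1 + patient$drift_rate * (fraction_index - 1)
  contrast <- df$contrast0 * g
  corr_mm <- df$corr_len0_mm / g

  xc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  zc <- (seq_len(d[3]) - 0.5) * sp[3]
  ex <- outer((xc - geom$center[1])^2 / geom$semiaxes[1]^2,
              (yc - geom$center[2])^2 / geom$semiaxes[2]^2, "+")
  msk <- array(FALSE, d)
  for (k in seq_len(d[3]))
    msk[, , k] <- ex + (zc[k] - geom$center[3])^2 / geom$semiaxes[3]^2 <= 1
  if (!any(msk)) stop("configuration error: empty ROI on this grid")

  # persistent per-patient anatomy: the same white-noise field underlies
  # every fraction (seed offset keeps it independent of the latent draws);
  # drift reshapes its autocorrelation, only imaging noise is fresh daily
  set.seed(as.integer((patient$seed + 524287) %% 2147483647))
  base_noise <- array(stats::rnorm(prod(d)), dim = d)
  set.seed(as.integer((patient$seed + 7919 * fraction_index) %% 2147483647))
  field <- gaussian_smooth_fft(base_noise, corr_mm / sp)
  field <- field / stats::sd(field)
  field <- field + (df$noise_sd / df$contrast0) * stats::rnorm(prod(d))
  if (patient$noise_style == "smooth")
    field <- gaussian_smooth_fft(field, df$smooth_sigma_mm / sp)
  # standardize against the in-ROI statistics, then soft-clip, so that in
  # the absence of fiducials no ROI voxel can stray 3 SD from the ROI mean
  field <- (field - mean(field[msk])) / stats::sd(field[msk])
  field <- df$clip * tanh(field / df$clip)
  vals <- df$base_level + contrast * field

  art <- NULL
  ctr <- patient$fiducial_centers_mm
  if (NROW(ctr) > 0) {
    mu <- mean(vals[msk]); sg <- stats::sd(vals[msk])
    rod_val <- mu + 8 * sg
    spoke_val <- mu + 7 * sg
    art_list <- list()
    for (f in seq_len(nrow(ctr))) {
      zl <- which(abs(zc - ctr[f, 3]) <= df$rod_halflength_mm)
      in_rod <- which(outer((xc - ctr[f, 1])^2, (yc - ctr[f, 2])^2, "+")
                      <= df$rod_radius_mm^2, arr.ind = TRUE)
      ci <- max(1L, min(d[1], as.integer(ceiling(ctr[f, 1] / sp[1]))))
      cj <- max(1L, min(d[2], as.integer(ceiling(ctr[f, 2] / sp[2]))))
      for (k in zl) {
        if (nrow(in_rod) > 0) {
          vals[cbind(in_rod, k)] <- rod_val
          art_list[[length(art_list) + 1L]] <- cbind(in_rod, k)
        }
        for (a in patient$spoke_angles[[f]]) {
          tip_x <- ctr[f, 1] + df$spoke_length_mm * cos(a)
          tip_y <- ctr[f, 2] + df$spoke_length_mm * sin(a)
          ti <- max(1L, min(d[1], as.integer(ceiling(tip_x / sp[1]))))
          tj <- max(1L, min(d[2], as.integer(ceiling(tip_y / sp[2]))))
          ln <- raster_line_2d(ci, cj, ti, tj)
          vals[cbind(ln, k)] <- spoke_val
          art_list[[length(art_list) + 1L]] <- cbind(ln, k)
        }
      }
    }
    if (length(art_list) > 0) {
      art <- unique(do.call(rbind, art_list))
      colnames(art) <- c("i", "j", "k")
    }
  }
  list(volume = image_volume(vals, sp),
       mask = roi_mask(msk, sp),
       fiducial_centers_mm = ctr,
       artifact_voxels = art)
}
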