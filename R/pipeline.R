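## End-to-end orchestration: simulate -> preprocess -> extract -> delta/bin
## -> label -> model, with every stage seeded and all tabular outputs
## written deterministically (rerunning the same config reproduces
## byte-identical CSV/JSON). Volumes are generated, processed and discarded
## one fraction at a time so cohort size is bounded by features, not images.

#' Preprocessing options for feature extraction
#'
#' @param quantizer `"lloyd_max"` or `"uniform"`.
#' @param collewet apply Collewet 3-sigma re-segmentation before
#'   quantization.
#' @param n_levels gray levels G (default 256).
#' @param radius_mm fiducial-artifact removal radius (default 5).
#' @param target_mm isotropic resampling target (default 1).
#' @param resample resample before artifact removal (default TRUE; keeps the
#'   5 mm circle geometry exact in mm).
#' @export
preprocess_options <- function(quantizer = c("lloyd_max", "uniform"),
                               collewet = TRUE, n_levels = 256L,
                               radius_mm = 5.0, target_mm = 1.0,
                               resample = TRUE) {
  quantizer <- match.arg(quantizer)
  list(quantizer = quantizer, collewet = isTRUE(collewet),
       n_levels = as.integer(n_levels), radius_mm = radius_mm,
       target_mm = target_mm, resample = isTRUE(resample))
}

#' Preprocess one fraction and extract its feature vector
#'
#' Order of operations: isotropic resampling, fiducial-artifact removal,
#' optional Collewet re-segmentation, quantization, feature extraction.
#'
#' @param vol an [image_volume()].
#' @param mask an [roi_mask()].
#' @param fiducial_centers_mm fiducial positions in mm (may be NULL).
#' @param opts a [preprocess_options()] list.
#' @return list with `features` (named vector), `removed_fraction`,
#'   `mask_cc` (final ROI volume).
#' @export
process_fraction <- function(vol, mask, fiducial_centers_mm = NULL,
                             opts = preprocess_options()) {
  if (opts$resample) {
    rs <- resample_isotropic(vol, mask, opts$target_mm)
    vol <- rs$volume; mask <- rs$mask
  }
  ar <- remove_fiducial_artifacts(vol, mask, fiducial_centers_mm,
                                  radius_mm = opts$radius_mm)
  mask <- ar$cleaned_mask
  if (opts$collewet) mask <- collewet_resegment(vol, mask)
  q <- if (opts$quantizer == "lloyd_max")
    quantize_lloyd_max(vol, mask, opts$n_levels,
                       collewet_applied = opts$collewet)
  else
    quantize_uniform(vol, mask, opts$n_levels,
                     collewet_applied = opts$collewet)
  list(features = extract_features(vol, mask, q),
       removed_fraction = ar$removed_fraction,
       mask_cc = mask_volume_cc(mask))
}

#' Extract per-fraction features for a whole synthetic cohort
#'
#' @param patients list from [generate_cohort()].
#' @param opts a [preprocess_options()] list.
#' @param verbose print one line per patient.
#' @return list per patient: `features` (fractions x 49 matrix),
#'   `removed_fraction` (per fraction), plus the patient object.
#' @export
extract_cohort_features <- function(patients, opts = preprocess_options(),
                                    verbose = FALSE) {
  lapply(patients, function(p) {
    nfx <- p$schedule$n
    M <- matrix(NA_real_, nfx, length(feature_names()),
                dimnames = list(NULL, feature_names()))
    rem <- numeric(nfx)
    for (k in seq_len(nfx)) {
      fr <- generate_phantom_fraction(p, k)
      pf <- process_fraction(fr$volume, fr$mask, fr$fiducial_centers_mm,
                             opts)
      M[k, ] <- pf$features
      rem[k] <- pf$removed_fraction
    }
    if (verbose)
      message(p$patient_id, ": ", nfx, " fractions, mean removed ",
              round(100 * mean(rem), 1), "%")
    list(patient = p, features = M, removed_fraction = rem)
  })
}

#' Assemble the patient x bin x feature DRF array
#'
#' @param cohort_features list from [extract_cohort_features()].
#' @return list with `drf` (3D array), `missing` (patient x bin logical),
#'   `flagged` (list of dropped features per patient).
#' @export
build_drf_array <- function(cohort_features) {
  bins <- bed_bins()
  feats <- feature_names()
  np <- length(cohort_features)
  ids <- vapply(cohort_features, function(x) x$patient$patient_id, "")
  A <- array(NA_real_, c(np, length(bins), length(feats)),
             dimnames = list(ids, paste0("BED", bins), feats))
  miss <- matrix(TRUE, np, length(bins), dimnames = list(ids, paste0("BED", bins)))
  flagged <- vector("list", np)
  for (i in seq_len(np)) {
    bd <- bin_drfs(cohort_features[[i]]$features,
                   cohort_features[[i]]$patient$schedule, bins)
    A[i, , ] <- bd$values
    miss[i, ] <- bd$missing
    flagged[[i]] <- bd$flagged
  }
  list(drf = A, missing = miss, flagged = flagged)
}

#' Endpoint label matrices for a cohort
#'
#' @param patients list from [generate_cohort()].
#' @param endpoint `"acute_gu"`, `"subacute_gu"` or `"delta_ipss"`.
#' @return patients x bins 0/1 matrix (constant columns for bin-invariant
#'   endpoints).
#' @export
build_labels <- function(patients,
                         endpoint = c("acute_gu", "subacute_gu",
                                      "delta_ipss")) {
  endpoint <- match.arg(endpoint)
  bins <- bed_bins()
  ids <- vapply(patients, function(p) p$patient_id, "")
  L <- matrix(0L, length(patients), length(bins),
              dimnames = list(ids, paste0("BED", bins)))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    L[i, ] <- switch(endpoint,
      acute_gu = vapply(bins, function(b)
        label_acute_gu(p$toxicity_events, b), integer(1)),
      subacute_gu = rep(label_subacute_gu(p$toxicity_events), length(bins)),
      delta_ipss = rep(label_delta_ipss(p$ipss_initial, p$ipss_final)$category,
                       length(bins)))
  }
  L
}

#' Run the full delta-radiomics pipeline on a synthetic cohort
#'
#' @param config list with components `cohort` (arguments to
#'   [cohort_config()] or a ready config), `preprocess` (arguments to
#'   [preprocess_options()]), `model` (list: `endpoints`, `n_iter`, `seed`,
#'   `n_trees`, `method`).
#' @param out_dir output directory; created if missing. NULL skips writing.
#' @param cache_dir optional directory for content-addressed caching of the
#'   extracted feature tables (keyed by the cohort + preprocessing hash);
#'   reruns with the same configuration resume from the cache, since
#'   feature extraction dominates runtime.
#' @param verbose progress messages.
#' @return run manifest: config hash, file paths, and the in-memory model
#'   results (`models`), DRF array and labels.
#' @export
run_pipeline <- function(config, out_dir = NULL, cache_dir = NULL,
                         verbose = FALSE) {
  cc <- config$cohort
  if (!inherits(cc, "cohort_config")) cc <- do.call(cohort_config, cc)
  opts <- do.call(preprocess_options,
                  if (is.null(config$preprocess)) list() else config$preprocess)
  mc <- config$model
  if (is.null(mc)) mc <- list()
  endpoints <- if (is.null(mc$endpoints))
    c("acute_gu", "subacute_gu", "delta_ipss") else mc$endpoints
  n_iter <- if (is.null(mc$n_iter)) 1000L else as.integer(mc$n_iter)
  mseed <- if (is.null(mc$seed)) cc$seed + 1L else as.integer(mc$seed)
  n_trees <- if (is.null(mc$n_trees)) 500L else as.integer(mc$n_trees)
  method <- if (is.null(mc$method)) "bootstrap_loo" else mc$method

  cfg_hash <- digest::digest(list(cohort = unclass(cc), preprocess = opts,
                                  endpoints = endpoints, n_iter = n_iter,
                                  seed = mseed, n_trees = n_trees,
                                  method = method))
  patients <- generate_cohort(cc)
  stage_hash <- digest::digest(list(cohort = unclass(cc), preprocess = opts))
  cache_file <- if (!is.null(cache_dir))
    file.path(cache_dir, paste0("features-", stage_hash, ".rds"))
  if (!is.null(cache_dir) && file.exists(cache_file)) {
    if (verbose) message("resuming features from cache ", cache_file)
    feats <- readRDS(cache_file)
  } else {
    feats <- extract_cohort_features(patients, opts, verbose = verbose)
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(feats, cache_file)
    }
  }
  da <- build_drf_array(feats)

  models <- list()
  for (ep in endpoints) {
    labs <- build_labels(patients, ep)
    extra <- NULL
    if (ep == "delta_ipss") {
      extra <- matrix(vapply(patients, function(p) p$ipss_initial, 0),
                      ncol = 1, dimnames = list(rownames(labs),
                                                "IPSS_Baseline"))
    }
    models[[ep]] <- tryCatch(
      fit_endpoint_models(
        da$drf, labs, extra_covariates = extra, n_trees = n_trees,
        n_iter = n_iter, seed = mseed, method = method,
        eval_bins = mc$eval_bins),
      error = function(e) {
        # e.g. a cohort with no qualifying events has single-class labels;
        # record the endpoint as unevaluable instead of aborting the run
        structure(list(failed = TRUE, error = conditionMessage(e)),
                  class = "drf_models_failed")
      })
  }

  manifest <- list(config_hash = cfg_hash, endpoints = endpoints,
                   n_patients = cc$n_patients,
                   mean_removed_fraction =
                     mean(unlist(lapply(feats, `[[`, "removed_fraction"))),
                   models = models, drf = da, patients = patients,
                   features = feats)
  if (!is.null(out_dir)) {
    manifest$files <- write_run_outputs(manifest, out_dir)
  }
  invisible(manifest)
}

write_run_outputs <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()

  # long-format feature table
  rows <- do.call(rbind, lapply(manifest$features, function(fx) {
    nfx <- nrow(fx$features)
    data.frame(patient_id = fx$patient$patient_id,
               fraction = rep(seq_len(nfx), ncol(fx$features)),
               feature_name = rep(colnames(fx$features), each = nfx),
               value = as.vector(fx$features))
  }))
  files$features <- file.path(out_dir, "features.csv")
  write_table(rows, files$features)

  # long-format DRF matrix
  A <- manifest$drf$drf
  dn <- dimnames(A)
  drf_long <- data.frame(
    patient_id = rep(dn[[1]], times = length(dn[[2]]) * length(dn[[3]])),
    bin = rep(rep(dn[[2]], each = length(dn[[1]])), times = length(dn[[3]])),
    feature_name = rep(dn[[3]], each = length(dn[[1]]) * length(dn[[2]])),
    value = as.vector(A))
  files$drf <- file.path(out_dir, "drf.csv")
  write_table(drf_long, files$drf)

  # labels
  labs <- do.call(rbind, lapply(manifest$endpoints, function(ep) {
    L <- build_labels(manifest$patients, ep)
    data.frame(patient_id = rep(rownames(L), ncol(L)),
               endpoint = ep,
               bin = rep(colnames(L), each = nrow(L)),
               category = as.vector(L))
  }))
  files$labels <- file.path(out_dir, "labels.csv")
  write_table(labs, files$labels)

  # cohort manifest
  cohort_json <- lapply(manifest$patients, function(p) list(
    patient_id = p$patient_id,
    n_fractions = p$schedule$n, dose_per_fraction = p$schedule$d,
    drift_rate = p$drift_rate, outcome = p$outcome,
    ipss_initial = p$ipss_initial, ipss_final = p$ipss_final,
    events = p$toxicity_events))
  files$cohort <- file.path(out_dir, "cohort.json")
  jsonlite::write_json(cohort_json, files$cohort, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  # model reports
  report <- list(config_hash = manifest$config_hash)
  for (ep in manifest$endpoints) {
    m <- manifest$models[[ep]]
    if (inherits(m, "drf_models_failed")) {
      report[[ep]] <- list(evaluable = FALSE, error = m$error)
      next
    }
    report[[ep]] <- list(
      selected_features = m$selected_features,
      bins = lapply(m$per_bin, function(pb) {
        if (!isTRUE(pb$evaluable)) return(list(evaluable = FALSE))
        list(evaluable = TRUE, n = pb$n,
             coefficients = as.list(pb$coefficients),
             auc_median = pb$auc_median,
             auc_ci = pb$auc_ci)
      }))
  }
  files$models <- file.path(out_dir, "models.json")
  jsonlite::write_json(report, files$models, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  # bootstrap AUC long table (box-plot ready)
  auc_rows <- do.call(rbind, lapply(manifest$endpoints, function(ep) {
    m <- manifest$models[[ep]]
    if (inherits(m, "drf_models_failed")) return(NULL)
    do.call(rbind, lapply(names(m$per_bin), function(b) {
      pb <- m$per_bin[[b]]
      if (!isTRUE(pb$evaluable)) return(NULL)
      data.frame(endpoint = ep, bin = b,
                 iteration = seq_along(pb$auc), auc = pb$auc)
    }))
  }))
  if (is.null(auc_rows))
    auc_rows <- data.frame(endpoint = character(0), bin = character(0),
                           iteration = integer(0), auc = numeric(0))
  files$auc <- file.path(out_dir, "bootstrap_auc.csv")
  write_table(auc_rows, files$auc)
  files
}

#' @export
print.drf_models_failed <- function(x, ...) {
  cat("<drf_models> endpoint unevaluable:", x$error, "\n")
  invisible(x)
}

## deterministic CSV writer (fixed 15 significant digits, no row names)
write_table <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (j in which(num)) df[[j]] <- sprintf("%.15g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a YAML run configuration
#'
#' The file may contain `cohort`, `preprocess` and `model` sections whose
#' keys mirror [cohort_config()], [preprocess_options()] and the `model`
#' list of [run_pipeline()].
#'
#' @param path YAML file path.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$cohort$schedules))
    cfg$cohort$schedules <- lapply(cfg$cohort$schedules, unlist)
  cfg
}
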