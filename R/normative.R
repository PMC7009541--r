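# Voxelwise normative atlas: per-voxel MOGP fits over a masked grid with
# 5-fold cross-validation, out-of-fold deviation (Z) maps, MAE accuracy maps,
# prediction at arbitrary covariates, and prediction-median intensity
# normalization. No spatial smoothing happens anywhere in this module;
# neighbourhood context is the zeta module's job.

#' Sequential-order fold assignment
#'
#' Subjects are assigned in enrolment order: the subject at ordinal position p
#' (0-based) goes to fold `p %% n_folds`, i.e. every fifth subject shares a
#' fold. Order sensitivity is intended.
#'
#' @param subject_ids Character vector in enrolment order.
#' @param n_folds Number of folds (default 5).
#' @return Named integer vector of fold indices in `0..n_folds-1`.
#' @export
assign_folds <- function(subject_ids, n_folds = 5) {
  n <- length(subject_ids)
  if (n < n_folds) stop_arg("need at least %d subjects for %d folds", n_folds, n_folds)
  stats::setNames((seq_len(n) - 1L) %% as.integer(n_folds), subject_ids)
}

#' Configuration for atlas fitting
#'
#' @param n_folds Cross-validation folds (default 5, every-nth assignment).
#' @param rank Coregionalization rank.
#' @param noise White-noise model, `"coupled"` or `"independent"`.
#' @param n_restarts Optimizer restarts per voxel fit (1 by default for atlas
#'   work; raise for small problems).
#' @param seed Base seed for restart jitter.
#' @param maxit Optimizer iteration cap.
#' @param ard Per-input lengthscales.
#' @param final_fit Also fit an all-data model per voxel for deployment-style
#'   prediction of new subjects.
#' @param max_fail_frac Run-level error if more than this fraction of voxel
#'   fits fail.
#' @return List of class `atlas_config`.
#' @export
atlas_config <- function(n_folds = 5, rank = 2, noise = "coupled", n_restarts = 1,
                         seed = 1, maxit = 100, ard = FALSE, final_fit = FALSE,
                         max_fail_frac = 0.05) {
  structure(list(n_folds = n_folds, rank = rank, noise = noise,
                 n_restarts = n_restarts, seed = seed, maxit = maxit, ard = ard,
                 final_fit = final_fit, max_fail_frac = max_fail_frac),
            class = "atlas_config")
}

design_matrix <- function(covariates)
  cbind(pma = covariates$pma_weeks, ga = covariates$ga_weeks, sex = covariates$sex)

#' Fit a voxelwise normative atlas
#'
#' Fits one MOGP per masked voxel per training fold (voxels are independent;
#' results do not depend on traversal order) and stores out-of-fold predictive
#' means and standard deviations for every subject. Voxels that are constant
#' across the cohort in any channel are auto-excluded from the modelling mask
#' with a logged count; failed voxel fits are flagged and propagate NaN.
#'
#' @param cohort A `cohort`.
#' @param config An `atlas_config`.
#' @param verbose Print per-fold progress.
#' @return Object of class `normative_atlas`.
#' @export
fit_atlas <- function(cohort, config = atlas_config(), verbose = FALSE) {
  n <- nrow(cohort$covariates)
  if (n < 10) stop_arg("at least 10 subjects required, got %d", n)
  vox <- cohort$voxel_index
  nv <- length(vox)
  if (nv == 0) stop_arg("mask is empty")
  X <- design_matrix(cohort$covariates)
  Yall <- array(cohort$images, c(n, 5, prod(cohort$grid_shape)))[, , vox, drop = FALSE]
  # degenerate-voxel exclusion
  degen <- vapply(seq_len(nv), function(v)
    any(apply(Yall[, , v, drop = FALSE], 2, stats::sd) == 0), logical(1))
  if (any(degen)) {
    message(sprintf("excluding %d degenerate (constant) voxel(s) from mask", sum(degen)))
    vox <- vox[!degen]; Yall <- Yall[, , !degen, drop = FALSE]; nv <- length(vox)
  }
  folds <- assign_folds(cohort$covariates$subject_id, config$n_folds)
  oof_mean <- array(NA_real_, c(n, 5, nv))
  oof_sd <- array(NA_real_, c(n, 5, nv))          # noise-inclusive
  oof_sd_latent <- array(NA_real_, c(n, 5, nv))
  fits <- vector("list", config$n_folds)
  n_fail <- 0
  for (f in seq_len(config$n_folds) - 1L) {
    tr <- which(folds != f); te <- which(folds == f)
    fits_f <- vector("list", nv)
    for (v in seq_len(nv)) {
      fit <- tryCatch(
        mogp_fit(X[tr, , drop = FALSE], Yall[tr, , v], rank = config$rank,
                 noise = config$noise, n_restarts = config$n_restarts,
                 seed = derive_seed(config$seed, f * nv + v),
                 ard = config$ard, maxit = config$maxit),
        error = function(e) NULL)
      fits_f[[v]] <- fit
      if (is.null(fit)) { n_fail <- n_fail + 1; next }
      pn <- predict(fit, X[te, , drop = FALSE], include_noise = TRUE)
      pl <- predict(fit, X[te, , drop = FALSE], include_noise = FALSE)
      oof_mean[te, , v] <- pn$mean
      oof_sd[te, , v] <- pn$sd
      oof_sd_latent[te, , v] <- pl$sd
    }
    fits[[f + 1L]] <- fits_f
    if (verbose) message(sprintf("fold %d/%d done", f + 1, config$n_folds))
  }
  if (n_fail > config$max_fail_frac * nv * config$n_folds)
    stop_arg("%d of %d voxel fits failed (> %.0f%%)", n_fail,
             nv * config$n_folds, 100 * config$max_fail_frac)
  final <- NULL
  if (isTRUE(config$final_fit)) {
    final <- lapply(seq_len(nv), function(v)
      tryCatch(mogp_fit(X, Yall[, , v], rank = config$rank, noise = config$noise,
                        n_restarts = config$n_restarts,
                        seed = derive_seed(config$seed, 999000 + v),
                        ard = config$ard, maxit = config$maxit),
               error = function(e) NULL))
  }
  train_sd <- vapply(seq_len(nv), function(v) apply(Yall[, , v], 2, stats::sd),
                     numeric(5))                   # 5 x nv
  structure(list(mask = cohort$mask, grid_shape = cohort$grid_shape,
                 voxel_index = vox, fits = fits, final_fits = final,
                 folds = folds, config = config, covariates = cohort$covariates,
                 train_sd = train_sd, oof_mean = oof_mean, oof_sd = oof_sd,
                 oof_sd_latent = oof_sd_latent, n_failed = n_fail,
                 n_excluded = sum(degen),
                 pma_range = range(cohort$covariates$pma_weeks)),
            class = "normative_atlas")
}

check_extrapolation <- function(atlas, pma) {
  lo <- atlas$pma_range[1]; hi <- atlas$pma_range[2]
  if (any(pma < lo - 6 | pma > hi + 6))
    stop_arg("PMA %.1f is more than 6 weeks outside the training range [%.1f, %.1f]",
             pma[which(pma < lo - 6 | pma > hi + 6)[1]], lo, hi)
  if (any(pma < lo - 2 | pma > hi + 2))
    warning(sprintf("extrapolating more than 2 weeks outside training PMA range [%.1f, %.1f]",
                    lo, hi), call. = FALSE)
}

#' Predict at a batch of covariate rows for all masked voxels
#'
#' Uses the all-data fit when present, otherwise moment-matches the mixture
#' of the per-fold posteriors.
#'
#' @param atlas A `normative_atlas`.
#' @param X_new `n_query x 3` matrix of (pma_weeks, ga_weeks, sex) rows.
#' @param include_noise Include the noise share in the predictive SD.
#' @return List of `mean` and `sd` arrays, each `[n_query, 5, n_voxels]`.
#' @export
predict_voxels <- function(atlas, X_new, include_noise = TRUE) {
  X_new <- matrix(as.numeric(X_new), ncol = 3)
  check_extrapolation(atlas, X_new[, 1])
  nq <- nrow(X_new); nv <- length(atlas$voxel_index)
  mu <- array(NA_real_, c(nq, 5, nv)); va <- array(NA_real_, c(nq, 5, nv))
  if (!is.null(atlas$final_fits)) {
    for (v in seq_len(nv)) {
      fit <- atlas$final_fits[[v]]
      if (is.null(fit)) next
      p <- predict(fit, X_new, include_noise = include_noise)
      mu[, , v] <- p$mean; va[, , v] <- p$sd^2
    }
  } else {
    nf <- atlas$config$n_folds
    for (v in seq_len(nv)) {
      ms <- array(NA_real_, c(nq, 5, nf)); vs <- array(NA_real_, c(nq, 5, nf))
      for (f in seq_len(nf)) {
        fit <- atlas$fits[[f]][[v]]
        if (is.null(fit)) next
        p <- predict(fit, X_new, include_noise = include_noise)
        ms[, , f] <- p$mean; vs[, , f] <- p$sd^2
      }
      mu[, , v] <- apply(ms, c(1, 2), mean, na.rm = TRUE)
      # mixture moment matching over folds
      va[, , v] <- apply(vs + ms^2, c(1, 2), mean, na.rm = TRUE) - mu[, , v]^2
    }
  }
  list(mean = mu, sd = sqrt(pmax(va, 1e-24)))
}

vol_from_flat <- function(values, atlas, channel_dim = TRUE) {
  # values: [5, nv] -> [5, grid]; or [nv] -> grid
  gs <- atlas$grid_shape
  if (is.matrix(values)) {
    out <- array(0, c(nrow(values), gs))
    flat <- array(out, c(nrow(values), prod(gs)))
    flat[, atlas$voxel_index] <- values
    array(flat, c(nrow(values), gs))
  } else {
    out <- array(0, gs)
    out[atlas$voxel_index] <- values
    out
  }
}

#' Predicted image (and predictive SD) at arbitrary covariates
#'
#' @param atlas A `normative_atlas`.
#' @param covariates A single covariate row (`pma_weeks`, `ga_weeks`, `sex`).
#' @param include_noise Include the noise share in the predictive SD.
#' @return List of `mean` and `sd`, each a `[5, nx, ny, nz]` array (zero
#'   outside the mask). Warns when extrapolating more than 2 weeks beyond the
#'   training PMA range; refuses beyond 6.
#' @export
predict_image <- function(atlas, covariates, include_noise = TRUE) {
  X <- cbind(covariates$pma_weeks, covariates$ga_weeks, covariates$sex)
  p <- predict_voxels(atlas, X[1, , drop = FALSE], include_noise = include_noise)
  list(mean = vol_from_flat(matrix(p$mean[1, , ], nrow = 5), atlas),
       sd = vol_from_flat(matrix(p$sd[1, , ], nrow = 5), atlas))
}

#' Deviation (Z) map from observation and prediction
#'
#' `Z = (observed - predicted_mean) / predicted_sd` per channel and voxel; the
#' normative probability map. The predictive SD is floored at `1e-6` times the
#' channel's data SD; floored voxels are flagged in the `qc` attribute.
#'
#' @param observed `[5, nx, ny, nz]` observed volume.
#' @param predicted_mean,predicted_sd Matching prediction arrays.
#' @param mask Logical volume; Z is zero outside it.
#' @return `[5, nx, ny, nz]` Z array with attribute `qc` (count of floored
#'   voxels), class `deviation_map`.
#' @export
deviation_map <- function(observed, predicted_mean, predicted_sd, mask) {
  stopifnot(all(dim(observed) == dim(predicted_mean)),
            all(dim(observed) == dim(predicted_sd)))
  floor_sd <- 1e-6 * apply(matrix(observed, dim(observed)[1]), 1, stats::sd)
  sd_floored <- pmax(predicted_sd, array(floor_sd, dim(predicted_sd)))
  n_floored <- sum(predicted_sd < array(floor_sd, dim(predicted_sd)))
  z <- (observed - predicted_mean) / sd_floored
  mvol <- aperm(array(mask, c(dim(observed)[-1], 5)), c(4, 1, 2, 3))
  z[!mvol] <- 0
  z[!is.finite(z)] <- 0
  structure(z, qc = c(n_floored = n_floored), class = "deviation_map")
}

#' Out-of-fold deviation maps for every cohort subject
#'
#' Each subject's Z uses predictions from the fold whose training set excluded
#' that subject (out-of-fold discipline).
#'
#' @param atlas A `normative_atlas` fitted on `cohort`.
#' @param cohort The cohort the atlas was fitted on.
#' @param include_noise Use noise-inclusive predictive SD (default; the
#'   variant used for Z-scores).
#' @return Array `[n_subjects, 5, n_masked_voxels]` of Z values, with
#'   attribute `fold` recording each subject's held-out fold.
#' @export
cohort_deviation_maps <- function(atlas, cohort, include_noise = TRUE) {
  n <- nrow(cohort$covariates)
  obs <- array(cohort$images, c(n, 5, prod(cohort$grid_shape)))[, , atlas$voxel_index,
                                                               drop = FALSE]
  sd_used <- if (include_noise) atlas$oof_sd else atlas$oof_sd_latent
  z <- (obs - atlas$oof_mean) / sd_used
  structure(z, fold = atlas$folds)
}

#' Expand one subject's flat deviation map to a volume
#' @param z_flat `[5, nv]` matrix (one subject's rows of
#'   [cohort_deviation_maps()] output).
#' @param atlas The atlas defining the mask.
#' @return `[5, nx, ny, nz]` array.
#' @export
deviation_volume <- function(z_flat, atlas) vol_from_flat(z_flat, atlas)

#' Cross-validated mean-absolute-error map
#'
#' Out-of-fold MAE per voxel and channel, divided by that voxel/channel's
#' cohort SD (units of input-data standard deviation).
#'
#' @param atlas A `normative_atlas`.
#' @param cohort The cohort it was fitted on.
#' @return `[5, nv]` matrix of normalized MAE with attribute `qc_zero_sd`
#'   counting zero-SD voxels (reported as NaN).
#' @export
mae_map <- function(atlas, cohort) {
  n <- nrow(cohort$covariates)
  obs <- array(cohort$images, c(n, 5, prod(cohort$grid_shape)))[, , atlas$voxel_index,
                                                               drop = FALSE]
  mae <- apply(abs(atlas$oof_mean - obs), c(2, 3), mean)     # 5 x nv
  sdm <- atlas$train_sd
  zero <- sdm == 0
  sdm[zero] <- NA_real_
  structure(mae / sdm, qc_zero_sd = sum(zero))
}

#' Scale an observed image to the prediction median in ROIs
#'
#' One global scale factor per channel:
#' `observed * median(predicted over ROI) / median(observed over ROI)`,
#' a prediction-median intensity normalization.
#'
#' @param observed `[5, nx, ny, nz]` image.
#' @param atlas A `normative_atlas`.
#' @param covariates The subject's covariate row.
#' @param roi_mask Logical volume of ROI voxels (must lie in the atlas mask).
#' @return The scaled image with attribute `scale_factors` (length 5).
#' @export
normalize_intensity <- function(observed, atlas, covariates, roi_mask) {
  if (!all(atlas$mask[roi_mask])) stop_arg("ROI voxels must lie inside the brain mask")
  pred <- predict_image(atlas, covariates)$mean
  out <- observed
  fac <- numeric(5)
  for (ch in 1:5) {
    po <- pred[ch, , , ][roi_mask]
    oo <- observed[ch, , , ][roi_mask]
    mo <- stats::median(oo)
    if (mo == 0) stop_arg("observed ROI median is zero in channel %d", ch)
    fac[ch] <- stats::median(po) / mo
    out[ch, , , ] <- observed[ch, , , ] * fac[ch]
  }
  structure(out, scale_factors = fac)
}
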