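# Atlas persistence: one JSON record per voxel per fold holding the fitted
# hyperparameters, standardization statistics and training outputs, plus the
# shared design and configuration, so a saved atlas predicts identically to
# the in-memory one.

fit_to_record <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(kernel = list(linear_variance = fit$kernel$linear_variance,
                     rbf_variance = fit$kernel$rbf_variance,
                     rbf_lengthscale = fit$kernel$rbf_lengthscale,
                     white_variance = fit$kernel$white_variance),
       W = fit$coreg$W, kappa = fit$coreg$kappa, noise = fit$noise,
       x_center = fit$x_center, x_scale = fit$x_scale,
       y_center = fit$y_center, y_scale = fit$y_scale,
       Y = fit$Y, lml = fit$lml, rank = fit$rank)
}

record_to_fit <- function(rec, X) {
  if (is.null(rec) || is.null(rec$kernel)) return(NULL)
  W <- matrix(unlist(rec$W), nrow = length(rec$kappa))
  Y <- matrix(unlist(rec$Y), nrow = nrow(X))
  Xs <- sweep(sweep(X, 2, rec$x_center), 2, rec$x_scale, "/")
  Ys <- sweep(sweep(Y, 2, rec$y_center), 2, rec$y_scale, "/")
  structure(list(kernel = kernel_params(rec$kernel$linear_variance,
                                        rec$kernel$rbf_variance,
                                        rec$kernel$rbf_lengthscale,
                                        rec$kernel$white_variance),
                 coreg = coreg_params(W, rec$kappa), noise = rec$noise,
                 X = X, Y = Y, Xs = Xs, Ys = Ys,
                 x_center = rec$x_center, x_scale = rec$x_scale,
                 y_center = rec$y_center, y_scale = rec$y_scale,
                 lml = rec$lml, n_outputs = ncol(Y), rank = rec$rank),
            class = "mogp_fit")
}

#' Save a normative atlas as JSON
#' @param atlas A `normative_atlas`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
atlas_save <- function(atlas, path) {
  X <- design_matrix(atlas$covariates)
  folds01 <- unname(atlas$folds)
  obj <- list(format = "neonorm-atlas-1",
              config = unclass(atlas$config),
              covariates = as.list(atlas$covariates),  # column-wise for clean round trip
              folds = folds01,
              grid_shape = atlas$grid_shape,
              mask_index = which(atlas$mask),
              voxel_index = atlas$voxel_index,
              train_sd = atlas$train_sd,
              pma_range = atlas$pma_range,
              n_failed = atlas$n_failed, n_excluded = atlas$n_excluded,
              oof_mean = atlas$oof_mean, oof_sd = atlas$oof_sd,
              oof_sd_latent = atlas$oof_sd_latent,
              fold_fits = lapply(atlas$fits, function(ff) lapply(ff, fit_to_record)),
              final_fits = if (is.null(atlas$final_fits)) NULL else
                lapply(atlas$final_fits, fit_to_record))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a normative atlas saved by [atlas_save()]
#' @param path JSON path.
#' @return A `normative_atlas`.
#' @export
atlas_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!identical(obj$format, "neonorm-atlas-1"))
    stop_arg("%s is not a neonorm atlas file", path)
  cov <- data.frame(obj$covariates, stringsAsFactors = FALSE)
  X <- design_matrix(cov)
  folds <- stats::setNames(as.integer(obj$folds), cov$subject_id)
  nfolds <- obj$config$n_folds
  nv <- length(obj$voxel_index)
  arr3 <- function(x) array(unlist(x), c(nrow(cov), 5, nv))
  fits <- lapply(seq_len(nfolds), function(f) {
    Xf <- X[which(folds != (f - 1L)), , drop = FALSE]
    lapply(obj$fold_fits[[f]], function(rec) record_to_fit(rec, Xf))
  })
  final <- if (!is.null(obj$final_fits))
    lapply(obj$final_fits, function(rec) record_to_fit(rec, X)) else NULL
  mask <- array(FALSE, obj$grid_shape)
  mask[obj$mask_index] <- TRUE
  structure(list(mask = mask, grid_shape = obj$grid_shape,
                 voxel_index = obj$voxel_index, fits = fits, final_fits = final,
                 folds = folds,
                 config = do.call(atlas_config, obj$config[names(formals(atlas_config))
                                                           [names(formals(atlas_config)) %in%
                                                               names(obj$config)]]),
                 covariates = cov,
                 train_sd = matrix(unlist(obj$train_sd), 5, nv),
                 oof_mean = arr3(obj$oof_mean), oof_sd = arr3(obj$oof_sd),
                 oof_sd_latent = arr3(obj$oof_sd_latent),
                 n_failed = obj$n_failed, n_excluded = obj$n_excluded,
                 pma_range = obj$pma_range),
            class = "normative_atlas")
}
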