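# Atlas-level tests run on one shared small cohort/atlas to keep the suite
# fast; the fit happens once at file load.
co_n <- fix_small_cohort(n = 30, gs = c(4, 4, 4), noise_sd = 0.5,
                         subject_effect_sd = 0.25, seed = 13, n_labels = 1)
atlas_n <- fit_atlas(co_n, atlas_config(n_restarts = 1, seed = 2))

test_that("assign_folds is the sequential modular assignment", {
  ids <- sprintf("s%d", 0:9)
  f <- assign_folds(ids, 5)
  expect_equal(unname(f), rep(0:4, 2))
  expect_equal(names(which(f == 0)), c("s0", "s5"))
  f11 <- assign_folds(sprintf("s%d", 0:10), 5)
  expect_equal(as.vector(table(f11)), c(3L, 2L, 2L, 2L, 2L))
  # order sensitivity is intended
  expect_false(identical(assign_folds(rev(ids), 5)[ids], f[ids]))
  expect_error(assign_folds(ids[1:3], 5), "at least 5")
})

test_that("fit_atlas fits one model per masked voxel per fold, deterministically", {
  expect_equal(length(atlas_n$fits), 5)
  expect_equal(length(atlas_n$fits[[1]]), length(atlas_n$voxel_index))
  expect_equal(atlas_n$n_failed, 0)
  # single-voxel mask
  grid1 <- tissue_label_map(c(3, 3, 3), n_labels = 1)
  co1 <- fix_small_cohort(n = 15, gs = c(3, 3, 3), seed = 4, n_labels = 1)
  a1 <- fit_atlas(co1, atlas_config(n_restarts = 1, seed = 1))
  expect_equal(length(a1$fits[[1]]), 1)
  # determinism: same seed/config -> identical fitted parameters
  a2 <- fit_atlas(co1, atlas_config(n_restarts = 1, seed = 1))
  expect_identical(a1$fits[[2]][[1]]$kernel, a2$fits[[2]][[1]]$kernel)
  expect_identical(a1$oof_mean, a2$oof_mean)
  expect_error(fit_atlas(fix_small_cohort(n = 8, gs = c(3, 3, 3), n_labels = 1)),
               "at least 10")
})

test_that("degenerate voxels are excluded with a message", {
  co <- fix_small_cohort(n = 12, gs = c(4, 4, 4), seed = 5, n_labels = 1)
  co$images[, , 2, 2, 2] <- 7  # constant across the cohort in all channels
  v <- neonorm:::vox_index(c(2, 2, 2), co$grid_shape)
  expect_message(a <- fit_atlas(co, atlas_config(n_restarts = 1)), "degenerate")
  expect_equal(a$n_excluded, 1)
  expect_false(v %in% a$voxel_index)
})

test_that("deviation_map is (obs - mean) / sd with mask and floor handling", {
  gs <- c(3, 3, 3)
  mask <- array(TRUE, gs); mask[1, 1, 1] <- FALSE
  mean_a <- array(rnorm(5 * 27), c(5, gs))
  sd_a <- array(runif(5 * 27, 0.5, 2), c(5, gs))
  z0 <- deviation_map(mean_a, mean_a, sd_a, mask)
  expect_true(all(z0 == 0))
  obs <- mean_a + 2 * sd_a
  z2 <- deviation_map(obs, mean_a, sd_a, mask)
  mvol <- aperm(array(mask, c(gs, 5)), c(4, 1, 2, 3))
  expect_true(all(abs(z2[mvol] - 2) < 1e-12))
  expect_true(all(z2[!mvol] == 0))
})

test_that("out-of-fold Z is calibrated and respects fold discipline", {
  z <- cohort_deviation_maps(atlas_n, co_n)
  expect_equal(dim(z), c(30, 5, length(atlas_n$voxel_index)))
  # provenance: the fold attribute matches the sequential assignment
  expect_identical(attr(z, "fold"), assign_folds(co_n$covariates$subject_id, 5))
  # pooled Z approximates N(0,1): KS-style closeness on the pooled sample
  zs <- as.numeric(z)
  expect_lt(abs(mean(zs)), 0.1)
  expect_lt(abs(sd(zs) - 1), 0.15)
  ks <- suppressWarnings(ks.test(zs, "pnorm"))
  expect_lt(unname(ks$statistic), 0.05)  # D-statistic closeness, n ~ 1.2e4
})

test_that("predict_image is deterministic, smooth in PMA, and ordered in sd", {
  cov <- list(pma_weeks = 38, ga_weeks = 36, sex = 0)
  p1 <- predict_image(atlas_n, cov)
  p2 <- predict_image(atlas_n, cov)
  expect_identical(p1, p2)
  expect_true(all(matrix(p1$sd, 5)[, as.logical(atlas_n$mask)] > 0))
  pn <- predict_image(atlas_n, cov, include_noise = TRUE)
  pl <- predict_image(atlas_n, cov, include_noise = FALSE)
  expect_true(all(matrix(pn$sd, 5)[, as.logical(atlas_n$mask)] >
                    matrix(pl$sd, 5)[, as.logical(atlas_n$mask)]))
  # smoothness: finite differences of the mean w.r.t. PMA are bounded
  pmas <- seq(34, 42, by = 0.5)
  preds <- vapply(pmas, function(w)
    predict_image(atlas_n, list(pma_weeks = w, ga_weeks = 33, sex = 0))$mean[1, 2, 2, 2],
    numeric(1))
  expect_lt(max(abs(diff(preds) / 0.5)), 2)  # < 2 intensity units per week
  # extrapolation guard rails
  expect_warning(predict_image(atlas_n, list(pma_weeks = atlas_n$pma_range[2] + 4,
                                             ga_weeks = 38, sex = 0)), "extrapolat")
  expect_error(suppressWarnings(predict_image(atlas_n,
                                              list(pma_weeks = atlas_n$pma_range[2] + 7,
                                                   ga_weeks = 38, sex = 0))), "outside")
})

test_that("noise-free training data is reproduced at training covariates", {
  grid <- tissue_label_map(c(3, 3, 3), n_labels = 1)
  co <- generate_cohort(20, grid, noise_sd = 0.02, subject_effect_sd = 0, seed = 21)
  a <- fit_atlas(co, atlas_config(n_restarts = 1, seed = 3))
  s <- 7
  truth <- ground_truth_mean(co$spec, 1, co$covariates[s, ])
  p <- predict_image(a, co$covariates[s, ])
  got <- p$mean[, 2, 2, 2]
  expect_equal(got, truth, tolerance = 0.05)  # near-noise-free recovery
})

test_that("mae_map matches the folded-normal oracle for a mean predictor", {
  # predictor == training mean on N(0,1 ) data gives normalized MAE sqrt(2/pi)
  set.seed(33)
  n <- 4000
  y <- rnorm(n)
  mae <- mean(abs(y - mean(y))) / sd(y)
  expect_equal(mae, sqrt(2 / pi), tolerance = 0.05)
  m <- mae_map(atlas_n, co_n)
  expect_true(all(m >= 0))
  # a well-specified model beats the trivial bound at most voxels
  expect_gt(mean(m < 1), 0.95)
})

test_that("normalize_intensity applies a single median-ratio factor per channel", {
  roi <- array(FALSE, atlas_n$grid_shape)
  roi[2:3, 2:3, 2:3] <- TRUE
  roi <- roi & atlas_n$mask
  cov <- co_n$covariates[1, ]
  pred <- predict_image(atlas_n, cov)$mean
  out1 <- normalize_intensity(pred, atlas_n, cov, roi)
  expect_equal(unname(attr(out1, "scale_factors")), rep(1, 5), tolerance = 1e-12)
  out2 <- normalize_intensity(2 * pred, atlas_n, cov, roi)
  expect_equal(as.numeric(out2), as.numeric(pred), tolerance = 1e-12)
  # scale factor ignores voxels outside the ROI
  pert <- pred
  pert[, 1, 1, 1] <- 999
  out3 <- normalize_intensity(pert, atlas_n, cov, roi)
  expect_equal(attr(out3, "scale_factors"), attr(out1, "scale_factors"),
               tolerance = 1e-12)
  bad_roi <- array(TRUE, atlas_n$grid_shape)
  expect_error(normalize_intensity(pred, atlas_n, cov, bad_roi), "inside")
})

test_that("prematurity sensitivity: stronger generator slope, stronger fitted GA effect", {
  slopes <- c(0, 0.1)
  ga_eff <- vapply(slopes, function(ps) {
    sp <- growth_curve_spec(n_labels = 1, prematurity_slope = ps, sex_effect = 0)
    co <- generate_cohort(60, tissue_label_map(c(3, 3, 3), n_labels = 1),
                          spec = sp, noise_sd = 0.3, subject_effect_sd = 0.1,
                          seed = 31)
    a <- fit_atlas(co, atlas_config(n_restarts = 1, seed = 4))
    p1 <- predict_voxels(a, cbind(40, 32, 0))
    p2 <- predict_voxels(a, cbind(40, 38, 0))
    mean(abs(p2$mean - p1$mean) / 6)
  }, numeric(1))
  expect_gt(ga_eff[2], ga_eff[1])
})

test_that("atlas JSON round trip predicts identically", {
  path <- tempfile(fileext = ".json")
  atlas_save(atlas_n, path)
  a2 <- atlas_load(path)
  cov <- list(pma_weeks = 37.5, ga_weeks = 33, sex = 1)
  p1 <- predict_image(atlas_n, cov)
  p2 <- predict_image(a2, cov)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-12)
  expect_equal(p1$sd, p2$sd, tolerance = 1e-12)
  z1 <- cohort_deviation_maps(atlas_n, co_n)
  z2 <- cohort_deviation_maps(a2, co_n)
  expect_equal(as.numeric(z1), as.numeric(z2), tolerance = 1e-12)
  unlink(path)
})
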