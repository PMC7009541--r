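test_that("sample_covariates validates, reproduces, and hits the preterm fraction", {
  expect_error(sample_covariates(0), "positive")
  expect_error(sample_covariates(5, pma_range = c(10, 40)), "inside")
  a <- sample_covariates(50, seed = 1)
  b <- sample_covariates(50, seed = 1)
  expect_identical(a, b)
  expect_true(all(a$ga_weeks <= a$pma_weeks))
  expect_true(all(a$ga_weeks >= 20 & a$pma_weeks <= 46))
  expect_true(all(a$sex %in% 0:1))
  # binomial oracle: 1000 draws at p = 0.3, 95% interval ~ +/- 0.03; spec
  # allows +/- 0.05 to absorb the range-rejection bias
  big <- sample_covariates(1000, seed = 2, preterm_fraction = 0.3)
  expect_lt(abs(mean(big$ga_weeks < 37) - 0.3), 0.05)
})

test_that("ground_truth_mean follows its closed form", {
  sp0 <- growth_curve_spec(n_labels = 1, baseline = 10, linear_slope = 0,
                           sigmoid_amplitude = 0, prematurity_slope = 0,
                           sex_effect = 0)
  expect_equal(ground_truth_mean(sp0, 1, list(pma_weeks = 40, ga_weeks = 30, sex = 1)),
               rep(10, 5))
  # GA enters only through the prematurity term
  sp1 <- growth_curve_spec(n_labels = 1, prematurity_slope = 0)
  m_term <- ground_truth_mean(sp1, 1, list(pma_weeks = 40, ga_weeks = 40, sex = 0))
  m_prem <- ground_truth_mean(sp1, 1, list(pma_weeks = 40, ga_weeks = 30, sex = 0))
  expect_equal(m_term, m_prem)
  # logistic(0) = 1/2 at the midpoint
  sp2 <- growth_curve_spec(n_labels = 1, baseline = 1, linear_slope = 0.1,
                           sigmoid_amplitude = 2, sigmoid_midpoint = 36,
                           prematurity_slope = 0, sex_effect = 0)
  expect_equal(ground_truth_mean(sp2, 1, list(pma_weeks = 36, ga_weeks = 36, sex = 0)),
               rep(1 + 0.1 * 36 + 1, 5))
  expect_error(ground_truth_mean(sp0, 3, list(pma_weeks = 36, ga_weeks = 36, sex = 0)),
               "unknown label")
})

test_that("generate_cohort is exact without noise and bit-reproducible", {
  grid <- tissue_label_map(c(4, 4, 4), n_labels = 2)
  co0 <- generate_cohort(4, grid, noise_sd = 0, subject_effect_sd = 0, seed = 5)
  for (s in 1:4) for (v in which(grid > 0)) {
    truth <- ground_truth_mean(co0$spec, grid[v], co0$covariates[s, ])
    got <- array(co0$images, c(4, 5, 64))[s, , v]
    expect_equal(got, truth, tolerance = 1e-12)
  }
  # background exactly zero
  expect_true(all(array(co0$images, c(4, 5, 64))[, , which(grid == 0)] == 0))
  co1 <- generate_cohort(4, grid, seed = 5)
  co2 <- generate_cohort(4, grid, seed = 5)
  expect_identical(co1$images, co2$images)
  expect_error(generate_cohort(4, grid, noise_sd = -1), ">= 0")
})

test_that("residual SD about the true mean matches noise_sd (chi-square interval)", {
  grid <- tissue_label_map(c(3, 3, 3), n_labels = 1)
  n <- 500
  co <- generate_cohort(n, grid, noise_sd = 1, subject_effect_sd = 0, seed = 6)
  flat <- array(co$images, c(n, 5, 27))
  vox <- co$voxel_index
  for (v in vox[1]) {
    truth <- t(vapply(seq_len(n), function(s)
      ground_truth_mean(co$spec, grid[v], co$covariates[s, ]), numeric(5)))
    res <- flat[, , v] - truth
    sds <- apply(res, 2, sd)
    expect_true(all(sds > 0.9 & sds < 1.1))  # chi-square 99.9% band at n = 500
  }
})

test_that("hidden subject effects are the stated fingerprints", {
  grid <- tissue_label_map(c(4, 4, 4), n_labels = 1)
  co <- generate_cohort(6, grid, noise_sd = 0, subject_effect_sd = 0.7, seed = 8)
  # with zero noise, image - truth equals the hidden effect exactly
  flat <- array(co$images, c(6, 5, 64))
  v <- co$voxel_index[3]
  truth <- t(vapply(1:6, function(s)
    ground_truth_mean(co$spec, grid[v], co$covariates[s, ]), numeric(5)))
  expect_equal(flat[, , v] - truth, co$effects[, , 3], tolerance = 1e-12)
})

test_that("sphere_offsets enumerates the discrete ball", {
  expect_equal(nrow(sphere_offsets(1)), 7)
  expect_equal(nrow(sphere_offsets(2)), 33)   # 1 + 6 + 12 + 8 + 6
  off <- sphere_offsets(2)
  expect_true(all(rowSums(off^2) <= 4))
})

test_that("plant_lesions shifts exactly the masked voxels of one channel", {
  grid <- tissue_label_map(c(7, 7, 7), n_labels = 1)
  co <- generate_cohort(6, grid, seed = 9)
  ids <- co$covariates$subject_id[1:2]
  pl <- plant_lesions(co, ids, n_lesions_per_subject = 2, radius_voxels = 1,
                      amplitude_sd = 4, channel_index = 1, seed = 3)
  for (sid in ids) {
    s <- match(sid, co$covariates$subject_id)
    d <- pl$cohort$images[s, 1, , , ] - co$images[s, 1, , , ]
    lm <- pl$lesions[[sid]]
    expect_equal(unname(d[lm]), rep(4 * co$noise_sd, sum(lm)), tolerance = 1e-12)
    expect_true(all(d[!lm] == 0))
    expect_true(all(co$mask[lm]))                      # lesions inside mask
    for (ch in 2:5)
      expect_identical(pl$cohort$images[s, ch, , , ], co$images[s, ch, , , ])
  }
  # untouched subjects unchanged
  expect_identical(pl$cohort$images[4, , , , ], co$images[4, , , , ])
  # zero amplitude: images unchanged, masks still returned
  pl0 <- plant_lesions(co, ids, n_lesions_per_subject = 1, amplitude_sd = 0,
                       seed = 3)
  expect_identical(pl0$cohort$images, co$images)
  expect_length(pl0$lesions, 2)
  # impossible placement errors out
  tiny <- generate_cohort(4, tissue_label_map(c(3, 3, 3), n_labels = 1), seed = 1)
  expect_error(plant_lesions(tiny, tiny$covariates$subject_id[1],
                             radius_voxels = 3), "admissible")
})

test_that("generate_followup advances PMA and carries the fingerprint", {
  grid <- tissue_label_map(c(4, 4, 4), n_labels = 1)
  cov <- data.frame(subject_id = sprintf("S%02d", 1:6),
                    pma_weeks = seq(30, 35), ga_weeks = seq(28, 33),
                    sex = rep(0:1, 3), timepoint = 1L)
  co <- generate_cohort(6, grid, noise_sd = 0, subject_effect_sd = 1, seed = 2,
                        covariates = cov)
  fu <- generate_followup(co, interval_weeks = 6, effect_persistence = 1, seed = 4)
  expect_equal(fu$covariates$pma_weeks, cov$pma_weeks + 6)
  expect_equal(fu$covariates$ga_weeks, cov$ga_weeks)
  expect_identical(fu$covariates$sex, cov$sex)
  # persistence 1 + zero noise: deviation fields identical across timepoints
  expect_equal(fu$effects, co$effects, tolerance = 1e-12)
  # interval 0: covariates equal except the timepoint tag
  fu0 <- generate_followup(co, interval_weeks = 0, effect_persistence = 1, seed = 4)
  expect_equal(fu0$covariates$pma_weeks, cov$pma_weeks)
  expect_identical(fu0$covariates$timepoint, rep(2L, 6))
  expect_error(generate_followup(co, interval_weeks = 20), "exceeds 46")
  expect_error(generate_followup(co, effect_persistence = 1.5), "0, 1")
})

test_that("persistence 0 decorrelates hidden effects (null oracle)", {
  grid <- tissue_label_map(c(12, 12, 12), n_labels = 1)  # 1000 interior voxels
  cov <- data.frame(subject_id = "S01", pma_weeks = 32, ga_weeks = 30, sex = 0,
                    timepoint = 1L)
  co <- generate_cohort(1, grid, noise_sd = 0.5, subject_effect_sd = 1, seed = 3,
                        covariates = cov)
  fu <- generate_followup(co, interval_weeks = 5, effect_persistence = 0, seed = 6)
  r <- cor(as.numeric(co$effects[1, 1, ]), as.numeric(fu$effects[1, 1, ]))
  expect_lt(abs(r), 0.1)  # |r| < 1.96/sqrt(1000) with margin
  fu9 <- generate_followup(co, interval_weeks = 5, effect_persistence = 0.9, seed = 6)
  r9 <- cor(as.numeric(co$effects[1, 1, ]), as.numeric(fu9$effects[1, 1, ]))
  expect_gt(r9, 0.8)
})

test_that("tissue_label_map builds valid label grids", {
  g <- tissue_label_map(c(6, 5, 4), n_labels = 3)
  expect_equal(dim(g), c(6, 5, 4))
  expect_equal(sort(unique(as.integer(g))), 0:3)
  for (l in 1:3) expect_gte(sum(g == l), 1)
  # border is background
  expect_true(all(g[1, , ] == 0) && all(g[, 1, ] == 0) && all(g[, , 1] == 0))
  expect_error(tissue_label_map(c(2, 2, 2)), "too small")
  expect_error(tissue_label_map(c(4, 4)), "3 positive")
})
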