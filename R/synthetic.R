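# Synthetic neonatal cohorts with the statistical structure the normative
# model assumes: five channels (two intensity contrasts, three displacement
# components) on a labelled voxel grid, nonlinear age trajectories with a
# prematurity effect, stable per-subject deviation fields ("fingerprints"),
# correlated channel noise, and optional planted punctate lesions.

#' Sample a covariate table (PMA, GA, sex)
#'
#' Gestational age at birth is drawn preterm (24-36 weeks) with probability
#' `preterm_fraction`, otherwise at term (37-42 weeks); the scan follows birth
#' by an exponentially distributed postnatal interval (mean 2 weeks), and rows
#' falling outside `pma_range` are redrawn. This emulates a cohort scanned
#' mostly soon after birth with preterm infants scanned up to term-equivalent
#' age.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; sampling is bit-reproducible given it.
#' @param pma_range Admissible scan-age interval in weeks, inside [20, 46].
#' @param preterm_fraction Probability of preterm birth (GA < 37 weeks).
#' @return A `data.frame` with columns `subject_id`, `pma_weeks`, `ga_weeks`,
#'   `sex` (0/1) and `timepoint`.
#' @export
sample_covariates <- function(n, seed = 1, pma_range = c(26, 45),
                              preterm_fraction = 0.3) {
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop_arg("n must be a positive integer, got %s", deparse(n))
  if (length(pma_range) != 2 || pma_range[1] >= pma_range[2] ||
      pma_range[1] < 20 || pma_range[2] > 46)
    stop_arg("pma_range must be an increasing interval inside [20, 46]")
  if (preterm_fraction < 0 || preterm_fraction > 1)
    stop_arg("preterm_fraction must be in [0, 1]")
  n <- as.integer(n)
  with_seed(seed, {
    pma <- ga <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:1000) {
        preterm <- stats::runif(1) < preterm_fraction
        g <- if (preterm) stats::runif(1, 24, 36) else stats::runif(1, 37, 42)
        p <- g + stats::rexp(1, rate = 1 / 2)
        if (p >= pma_range[1] && p <= pma_range[2]) { ok <- TRUE; break }
      }
      if (!ok) stop_arg("could not sample PMA inside range after 1000 tries")
      pma[i] <- p; ga[i] <- g
    }
    sex <- stats::rbinom(n, 1, 0.5)
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               pma_weeks = pma, ga_weeks = ga, sex = sex, timepoint = 1L,
               stringsAsFactors = FALSE)
  })
}

validate_covariates <- function(cov) {
  need <- c("subject_id", "pma_weeks", "ga_weeks", "sex")
  miss <- setdiff(need, names(cov))
  if (length(miss)) stop_arg("covariate table missing column(s): %s",
                             paste(miss, collapse = ", "))
  bad <- which(!(cov$ga_weeks >= 20 & cov$ga_weeks <= cov$pma_weeks &
                   cov$pma_weeks <= 46))
  if (length(bad))
    stop_arg("covariate row %d violates 20 <= ga <= pma <= 46 (ga=%.1f, pma=%.1f)",
             bad[1], cov$ga_weeks[bad[1]], cov$pma_weeks[bad[1]])
  if (!all(cov$sex %in% c(0, 1))) stop_arg("sex must be coded 0/1")
  invisible(cov)
}

#' Block-structured tissue label map
#'
#' Builds a labelled grid: a background border (label 0, excluded from all
#' modelling) around an interior split into `n_labels` slabs along x, standing
#' in for tissue classes with distinct growth trajectories.
#'
#' @param grid_shape Three positive integers.
#' @param n_labels Number of tissue classes (>= 1).
#' @param border Background margin in voxels.
#' @return Integer 3-D array of labels, class `tissue_label_map`.
#' @export
tissue_label_map <- function(grid_shape, n_labels = 3, border = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    stop_arg("grid_shape must be 3 positive integers")
  if (any(grid_shape <= 2 * border))
    stop_arg("grid too small for border %d", border)
  interior <- grid_shape - 2L * border
  if (interior[1] < n_labels)
    stop_arg("interior x extent %d cannot hold %d labels", interior[1], n_labels)
  lab <- array(0L, grid_shape)
  xs <- (border + 1):(grid_shape[1] - border)
  slab <- pmin(as.integer(ceiling(seq_along(xs) * n_labels / length(xs))), n_labels)
  for (i in seq_along(xs))
    lab[xs[i], (border + 1):(grid_shape[2] - border),
        (border + 1):(grid_shape[3] - border)] <- slab[i]
  structure(lab, class = c("tissue_label_map", "array"))
}

#' Growth-curve specification for the generator
#'
#' Each (label, channel) mean trajectory is
#' `baseline + slope * pma + amplitude * logistic((pma - midpoint)/width) +
#'  prematurity_slope * (pma - ga) + sex_effect * sex`,
#' mirroring the smooth sigmoidal-plus-linear growth the voxel models target
#' while staying analytically known for recovery tests.
#'
#' @param n_labels Number of tissue labels.
#' @param baseline,linear_slope,sigmoid_amplitude,sigmoid_midpoint,sigmoid_width,
#'   prematurity_slope,sex_effect Either `n_labels x 5` matrices or scalars /
#'   5-vectors recycled across labels. Units: intensity per week for slopes;
#'   weeks for midpoint/width.
#' @param channel_correlation A 5x5 positive-definite correlation matrix for
#'   the observation noise (shared across labels), or a list of one per label.
#' @return Object of class `growth_curve_spec`.
#' @export
growth_curve_spec <- function(n_labels = 3,
                              baseline = NULL, linear_slope = NULL,
                              sigmoid_amplitude = NULL, sigmoid_midpoint = 36,
                              sigmoid_width = 2, prematurity_slope = NULL,
                              sex_effect = 0.1, channel_correlation = NULL) {
  as_mat <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.matrix(x)) { stopifnot(nrow(x) == n_labels, ncol(x) == 5); return(x) }
    matrix(rep(x, length.out = 5), n_labels, 5, byrow = TRUE)
  }
  baseline <- as_mat(baseline, t(vapply(seq_len(n_labels),
                                        function(l) 8 + 2 * l + (1:5), numeric(5))))
  linear_slope <- as_mat(linear_slope, c(0.08, 0.08, 0.02, 0.02, 0.02))
  sigmoid_amplitude <- as_mat(sigmoid_amplitude, c(2, -2, 0.5, 0.5, 0.5))
  sigmoid_midpoint <- as_mat(sigmoid_midpoint, 36)
  sigmoid_width <- as_mat(sigmoid_width, 2)
  prematurity_slope <- as_mat(prematurity_slope, c(0.05, 0.05, 0.01, 0.01, 0.01))
  sex_effect <- as_mat(sex_effect, 0.1)
  if (is.null(channel_correlation)) {
    channel_correlation <- diag(5)
    channel_correlation[1, 2] <- channel_correlation[2, 1] <- 0.3
    channel_correlation[3:5, 3:5][upper.tri(diag(3))] <- 0.2
    channel_correlation[3:5, 3:5][lower.tri(diag(3))] <- 0.2
  }
  if (!is.list(channel_correlation))
    channel_correlation <- rep(list(channel_correlation), n_labels)
  for (Rm in channel_correlation) {
    if (any(abs(diag(Rm) - 1) > 1e-12)) stop_arg("channel_correlation needs unit diagonal")
    if (min(eigen(Rm, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop_arg("channel_correlation must be positive definite")
  }
  structure(list(n_labels = n_labels, baseline = baseline,
                 linear_slope = linear_slope, sigmoid_amplitude = sigmoid_amplitude,
                 sigmoid_midpoint = sigmoid_midpoint, sigmoid_width = sigmoid_width,
                 prematurity_slope = prematurity_slope, sex_effect = sex_effect,
                 channel_correlation = channel_correlation),
            class = "growth_curve_spec")
}

#' Noise-free mean trajectory for one label at given covariates
#'
#' @param spec A `growth_curve_spec`.
#' @param label Tissue label in `1..n_labels`.
#' @param covariates One covariate row (list/data.frame with `pma_weeks`,
#'   `ga_weeks`, `sex`).
#' @return Numeric 5-vector, one value per channel.
#' @export
ground_truth_mean <- function(spec, label, covariates) {
  if (!label %in% seq_len(spec$n_labels))
    stop_arg("unknown label %s (spec has labels 1..%d)", label, spec$n_labels)
  pma <- covariates$pma_weeks; ga <- covariates$ga_weeks; sex <- covariates$sex
  l <- label
  as.numeric(spec$baseline[l, ] + spec$linear_slope[l, ] * pma +
    spec$sigmoid_amplitude[l, ] *
      stats::plogis((pma - spec$sigmoid_midpoint[l, ]) / spec$sigmoid_width[l, ]) +
    spec$prematurity_slope[l, ] * (pma - ga) + spec$sex_effect[l, ] * sex)
}

#' Channel names used throughout the package
#' @return Character vector of the five channel names.
#' @export
channel_names <- function() c("intensity1", "intensity2", "disp_x", "disp_y", "disp_z")

# Default synthetic affine: axis stretches growing linearly with PMA plus
# small shears; rotation identity, translation zero (both ignored by the model).
synthetic_affine <- function(pma, jitter = c(0, 0, 0, 0, 0, 0)) {
  stretch <- c(1 + 0.020 * (pma - 26), 1 + 0.018 * (pma - 26),
               1 + 0.022 * (pma - 26)) + jitter[1:3]
  shear <- c(0.01, 0.005, 0.008) * (pma - 26) / 19 + jitter[4:6]
  U <- diag(stretch)
  U[1, 2] <- shear[1] * U[1, 1]; U[1, 3] <- shear[2] * U[1, 1]
  U[2, 3] <- shear[3] * U[2, 2]
  cbind(U, c(0, 0, 0))
}

#' Generate a synthetic multi-channel cohort
#'
#' Per voxel v (label l), channel c and subject s the observation is
#' `y = mean(l, c, x_s) + u_s(v, c) + eps`, where `u_s ~ N(0, subject_effect_sd^2)`
#' is fixed per subject (the deviation fingerprint) and `eps ~ N(0, noise_sd^2)`
#' is drawn with the label's cross-channel correlation. Background voxels are
#' exactly zero.
#'
#' @param n Number of subjects (ignored if `covariates` given).
#' @param grid A `tissue_label_map`.
#' @param spec A `growth_curve_spec`.
#' @param noise_sd Observation noise SD (>= 0).
#' @param subject_effect_sd SD of the stable per-subject effect field (>= 0).
#' @param seed Integer seed.
#' @param covariates Optional covariate table overriding internal sampling.
#' @return Object of class `cohort`: covariates, `images` array
#'   `[subject, channel, x, y, z]`, logical `mask`, `labels`, per-subject 3x4
#'   `affines`, `channel_names`, the generation parameters, and the hidden
#'   per-subject `effects` array (for test assertions only).
#' @export
generate_cohort <- function(n, grid, spec = growth_curve_spec(), noise_sd = 1,
                            subject_effect_sd = 0.5, seed = 1, covariates = NULL) {
  if (noise_sd < 0 || subject_effect_sd < 0)
    stop_arg("noise_sd and subject_effect_sd must be >= 0")
  if (is.null(covariates))
    covariates <- sample_covariates(n, seed = derive_seed(seed, 1))
  validate_covariates(covariates)
  n <- nrow(covariates)
  gs <- dim(grid)
  mask <- grid > 0
  vox <- which(mask)                       # linear indices into the grid
  labs <- as.integer(grid[vox])
  nv <- length(vox)
  if (nv == 0) stop_arg("mask is empty")
  with_seed(derive_seed(seed, 2), {
    u <- array(stats::rnorm(n * 5 * nv, 0, subject_effect_sd), c(n, 5, nv))
    eps <- array(0, c(n, 5, nv))
    for (l in seq_len(spec$n_labels)) {
      sel <- which(labs == l)
      if (!length(sel)) next
      ch <- chol(spec$channel_correlation[[l]])
      z <- matrix(stats::rnorm(n * length(sel) * 5), n * length(sel), 5)
      e <- (z %*% ch) * noise_sd
      eps[, , sel] <- aperm(array(e, c(n, length(sel), 5)), c(1, 3, 2))
    }
    flat <- array(0, c(n, 5, prod(gs)))
    for (s in seq_len(n)) {
      mu <- t(vapply(seq_len(spec$n_labels), function(l)
        ground_truth_mean(spec, l, covariates[s, ]), numeric(5)))  # n_labels x 5
      flat[s, , vox] <- t(mu[labs, , drop = FALSE])
    }
    flat[, , vox] <- flat[, , vox, drop = FALSE] + u + eps
    images <- array(flat, c(n, 5, gs))
    affines <- lapply(seq_len(n), function(s)
      synthetic_affine(covariates$pma_weeks[s],
                       jitter = stats::rnorm(6, 0, c(0.01, 0.01, 0.01, 0.005, 0.005, 0.005))))
    structure(list(covariates = covariates, images = images, mask = mask,
                   labels = grid, affines = affines,
                   channel_names = channel_names(), noise_sd = noise_sd,
                   subject_effect_sd = subject_effect_sd, spec = spec,
                   grid_shape = gs, effects = u, voxel_index = vox, seed = seed),
              class = "cohort")
  })
}

#' Restrict a cohort to a subset of subjects
#' @param cohort A `cohort`.
#' @param idx Integer row indices or character subject ids.
#' @return A `cohort` containing only those subjects (enrolment order kept).
#' @export
subset_cohort <- function(cohort, idx) {
  if (is.character(idx)) idx <- match(idx, cohort$covariates$subject_id)
  if (anyNA(idx)) stop_arg("unknown subject id(s)")
  out <- cohort
  out$covariates <- cohort$covariates[idx, , drop = FALSE]
  rownames(out$covariates) <- NULL
  out$images <- cohort$images[idx, , , , , drop = FALSE]
  out$affines <- cohort$affines[idx]
  if (!is.null(cohort$effects))
    out$effects <- cohort$effects[idx, , , drop = FALSE]
  out
}

#' Integer offsets of a discrete sphere
#' @param radius Sphere radius in voxels.
#' @return Integer matrix of (dx, dy, dz) with `dx^2+dy^2+dz^2 <= radius^2`.
#' @export
sphere_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, ])
}

#' Plant punctate lesions into a cohort
#'
#' Adds `amplitude_sd * noise_sd` to one channel inside spherical masks whose
#' full extent lies inside the brain mask, emulating punctate white matter
#' lesions visible on a single contrast.
#'
#' @param cohort A `cohort`.
#' @param subject_ids Subjects to lesion (character ids).
#' @param n_lesions_per_subject Lesions per subject.
#' @param radius_voxels Sphere radius (>= 1).
#' @param amplitude_sd Effect size in units of the cohort's `noise_sd`; must be
#'   nonzero for a meaningful lesion set (0 is allowed and leaves images
#'   unchanged).
#' @param channel_index Channel receiving the lesions (default 1, the first
#'   intensity contrast).
#' @param seed Integer seed.
#' @return List with the modified `cohort` and `lesions`, a named list of
#'   logical lesion-mask volumes per lesioned subject (class `lesion_set` with
#'   `amplitude_sd` and `channel_index` attributes).
#' @export
plant_lesions <- function(cohort, subject_ids, n_lesions_per_subject = 3,
                          radius_voxels = 1, amplitude_sd = 4, channel_index = 1,
                          seed = 1) {
  if (radius_voxels < 1) stop_arg("radius_voxels must be >= 1")
  off <- sphere_offsets(radius_voxels)
  gs <- cohort$grid_shape
  coords <- which(cohort$mask, arr.ind = TRUE)
  # centres whose full sphere stays inside the mask
  ok <- vapply(seq_len(nrow(coords)), function(i) {
    pts <- sweep(off, 2, coords[i, ], "+")
    all(pts >= 1) && all(pts[, 1] <= gs[1] & pts[, 2] <= gs[2] & pts[, 3] <= gs[3]) &&
      all(cohort$mask[pts])
  }, logical(1))
  centres_pool <- coords[ok, , drop = FALSE]
  if (nrow(centres_pool) == 0)
    stop_arg("no admissible lesion centre: mask cannot contain a radius-%g sphere",
             radius_voxels)
  lesions <- list()
  shift <- amplitude_sd * cohort$noise_sd
  with_seed(derive_seed(seed, 3), {
    for (sid in subject_ids) {
      s <- match(sid, cohort$covariates$subject_id)
      if (is.na(s)) stop_arg("unknown subject id %s", sid)
      lmask <- array(FALSE, gs)
      placed <- 0; tries <- 0
      while (placed < n_lesions_per_subject && tries < 100 * n_lesions_per_subject) {
        tries <- tries + 1
        ci <- sample.int(nrow(centres_pool), 1)
        pts <- sweep(off, 2, centres_pool[ci, ], "+")
        if (any(lmask[pts])) next  # keep lesions disjoint
        lmask[pts] <- TRUE
        placed <- placed + 1
      }
      if (placed < n_lesions_per_subject)
        stop_arg("could not place %d disjoint lesions for %s after bounded retries",
                 n_lesions_per_subject, sid)
      li <- which(lmask)
      cohort$images[s, channel_index, , , ][li] <-
        cohort$images[s, channel_index, , , ][li] + shift
      lesions[[sid]] <- lmask
    }
  })
  structure(list(cohort = cohort,
                 lesions = structure(lesions, amplitude_sd = amplitude_sd,
                                     channel_index = channel_index,
                                     class = "lesion_set")),
            names = c("cohort", "lesions"))
}

#' Generate a follow-up timepoint for existing subjects
#'
#' PMA advances by `interval_weeks`; the hidden subject effect persists as
#' `u(t2) = rho * u(t1) + sqrt(1 - rho^2) * fresh`, so `effect_persistence = 1`
#' carries the fingerprint over unchanged and 0 replaces it.
#'
#' @param cohort A `cohort` (first timepoint).
#' @param subject_ids Subjects to rescan (default all).
#' @param interval_weeks Weeks between scans (>= 0).
#' @param effect_persistence Correlation rho of the subject effect across
#'   timepoints, in [0, 1].
#' @param seed Integer seed.
#' @return A `cohort` for the second timepoint (timepoint tag 2).
#' @export
generate_followup <- function(cohort, subject_ids = cohort$covariates$subject_id,
                              interval_weeks = 8, effect_persistence = 0.9,
                              seed = 1) {
  if (effect_persistence < 0 || effect_persistence > 1)
    stop_arg("effect_persistence must be in [0, 1]")
  sel <- match(subject_ids, cohort$covariates$subject_id)
  if (anyNA(sel)) stop_arg("unknown subject id(s)")
  cov2 <- cohort$covariates[sel, , drop = FALSE]
  cov2$pma_weeks <- cov2$pma_weeks + interval_weeks
  if (any(cov2$pma_weeks > 46))
    stop_arg("PMA after increment exceeds 46 weeks for %s",
             cov2$subject_id[which(cov2$pma_weeks > 46)[1]])
  cov2$timepoint <- 2L
  rownames(cov2) <- NULL
  n <- nrow(cov2); nv <- length(cohort$voxel_index)
  gs <- cohort$grid_shape
  labs <- as.integer(cohort$labels[cohort$voxel_index])
  spec <- cohort$spec
  with_seed(derive_seed(seed, 4), {
    rho <- effect_persistence
    fresh <- array(stats::rnorm(n * 5 * nv, 0, cohort$subject_effect_sd), c(n, 5, nv))
    u2 <- rho * cohort$effects[sel, , , drop = FALSE] + sqrt(1 - rho^2) * fresh
    eps <- array(0, c(n, 5, nv))
    for (l in seq_len(spec$n_labels)) {
      vsel <- which(labs == l)
      if (!length(vsel)) next
      ch <- chol(spec$channel_correlation[[l]])
      z <- matrix(stats::rnorm(n * length(vsel) * 5), n * length(vsel), 5)
      e <- (z %*% ch) * cohort$noise_sd
      eps[, , vsel] <- aperm(array(e, c(n, length(vsel), 5)), c(1, 3, 2))
    }
    flat <- array(0, c(n, 5, prod(gs)))
    for (s in seq_len(n)) {
      mu <- t(vapply(seq_len(spec$n_labels), function(l)
        ground_truth_mean(spec, l, cov2[s, ]), numeric(5)))
      flat[s, , cohort$voxel_index] <- t(mu[labs, , drop = FALSE])
    }
    flat[, , cohort$voxel_index] <- flat[, , cohort$voxel_index, drop = FALSE] + u2 + eps
    affines <- lapply(seq_len(n), function(s)
      synthetic_affine(cov2$pma_weeks[s],
                       jitter = stats::rnorm(6, 0, c(0.01, 0.01, 0.01, 0.005, 0.005, 0.005))))
    structure(list(covariates = cov2, images = array(flat, c(n, 5, gs)),
                   mask = cohort$mask, labels = cohort$labels, affines = affines,
                   channel_names = cohort$channel_names, noise_sd = cohort$noise_sd,
                   subject_effect_sd = cohort$subject_effect_sd, spec = spec,
                   grid_shape = gs, effects = u2, voxel_index = cohort$voxel_index,
                   seed = seed),
              class = "cohort")
  })
}
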