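# Lesion-detection evaluation (per-subject ROC/AUC for three scoring methods,
# Friedman + post hoc Wilcoxon comparisons, AUC-vs-age dependence) and
# longitudinal fingerprint identification from deviation-map correlations.

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' `AUC = P(score_lesion > score_background) + 0.5 * P(tie)`, computed exactly
#' with midranks; no threshold grid is involved.
#'
#' @param scores Numeric volume (or vector) of voxel scores.
#' @param lesion_mask Logical volume/vector of positive voxels.
#' @param brain_mask Logical volume/vector delimiting the evaluation region;
#'   negatives are brain voxels outside the lesion mask.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, lesion_mask, brain_mask = NULL) {
  s <- as.numeric(scores)
  pos <- as.logical(lesion_mask)
  keep <- if (is.null(brain_mask)) rep(TRUE, length(s)) else as.logical(brain_mask)
  s <- s[keep]; pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop_arg("ROC undefined: need both lesion and background voxels (got %d / %d)",
             n1, n0)
  r <- rank(s)  # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Covariate-blind leave-one-out sample Z-score
#'
#' The simple sample Z: per voxel and channel, the subject's value minus the
#' mean of all other subjects, over their SD. Covariates are ignored entirely.
#'
#' @param cohort A `cohort`.
#' @param subject Subject id (character) or row index.
#' @return `[5, nx, ny, nz]` Z array (zero outside mask, NaN at zero-SD voxels
#'   with a `qc_zero_sd` attribute count).
#' @export
sample_zscore <- function(cohort, subject) {
  n <- nrow(cohort$covariates)
  if (n < 3) stop_arg("cohort must have at least 3 subjects")
  s <- if (is.character(subject)) match(subject, cohort$covariates$subject_id)
  else as.integer(subject)
  if (is.na(s) || s < 1 || s > n) stop_arg("unknown subject")
  gs <- cohort$grid_shape
  flat <- array(cohort$images, c(n, 5, prod(gs)))
  x <- flat[s, , , drop = FALSE]; dim(x) <- c(5, prod(gs))
  sums <- apply(flat, c(2, 3), sum)
  sq <- apply(flat^2, c(2, 3), sum)
  m_loo <- (sums - x) / (n - 1)
  var_loo <- (sq - x^2 - (n - 1) * m_loo^2) / (n - 2)
  sd_loo <- sqrt(pmax(var_loo, 0))
  z <- (x - m_loo) / sd_loo
  zero <- sd_loo <= 1e-6 * pmax(abs(m_loo), 1)  # degenerate (cancellation floor ~ sqrt(eps)*|m|)
  z[zero] <- NaN
  mflat <- as.logical(cohort$mask)
  z[, !mflat] <- 0
  structure(array(z, c(5, gs)), qc_zero_sd = sum(zero[, mflat]))
}

#' Compare per-subject AUCs across scoring methods
#'
#' Friedman test on within-subject ranks; when significant at `alpha`,
#' pairwise Wilcoxon signed-rank tests on the AUC differences (exact for
#' n <= 25 without ties, normal approximation with continuity correction
#' above).
#'
#' @param auc A numeric `n_subjects x n_methods` matrix with column names.
#' @param alpha Significance level gating the post hoc tests.
#' @param alternative Passed to the Wilcoxon tests (default two-sided).
#' @return List with `friedman` (statistic, df, p), `posthoc` (data frame or
#'   NULL), and `median_auc` per method.
#' @export
compare_methods <- function(auc, alpha = 0.05, alternative = "two.sided") {
  auc <- as.matrix(auc)
  n <- nrow(auc); k <- ncol(auc)
  if (n < 6) stop_arg("need at least 6 subjects, got %d", n)
  if (k < 3) stop_arg("need at least 3 methods, got %d", k)
  if (is.null(colnames(auc))) colnames(auc) <- paste0("method", seq_len(k))
  if (all(apply(auc, 1, function(r) length(unique(r)) == 1))) {
    fr <- list(statistic = 0, df = k - 1, p.value = 1)
  } else {
    ft <- stats::friedman.test(auc)
    fr <- list(statistic = unname(ft$statistic), df = unname(ft$parameter),
               p.value = ft$p.value)
  }
  posthoc <- NULL
  if (fr$p.value < alpha) {
    pairs <- utils::combn(k, 2)
    posthoc <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      d <- auc[, b] - auc[, a]
      wt <- suppressWarnings(stats::wilcox.test(auc[, b], auc[, a], paired = TRUE,
                                                alternative = alternative,
                                                exact = n <= 25))
      data.frame(method1 = colnames(auc)[a], method2 = colnames(auc)[b],
                 W = unname(wt$statistic), p.value = wt$p.value,
                 median_gain = stats::median(d), stringsAsFactors = FALSE)
    }))
  }
  list(friedman = fr, posthoc = posthoc,
       median_auc = apply(auc, 2, stats::median), alpha = alpha)
}

#' Spearman correlation between age at scan and per-subject AUC
#'
#' @param auc `n x n_methods` matrix of per-subject AUCs.
#' @param pma Numeric vector of PMA at scan (weeks), aligned with rows.
#' @return Data frame with method, rho, p.value (NA when AUCs are constant).
#' @export
auc_age_dependence <- function(auc, pma) {
  auc <- as.matrix(auc)
  if (nrow(auc) < 5) stop_arg("need at least 5 subjects")
  do.call(rbind, lapply(seq_len(ncol(auc)), function(j) {
    a <- auc[, j]
    if (stats::sd(a) == 0)
      return(data.frame(method = colnames(auc)[j], rho = NA_real_,
                        p.value = NA_real_, stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(pma, a, method = "spearman"))
    data.frame(method = colnames(auc)[j], rho = unname(ct$estimate),
               p.value = ct$p.value, stringsAsFactors = FALSE)
  }))
}

#' Identify subjects from the correlation of their deviation maps
#'
#' For every follow-up map, Pearson correlations (over mask voxels, each
#' channel separately) against all candidate maps are ranked; the subject is
#' identified when their own first-timepoint map ranks first. Rank ties are
#' broken pessimistically (a tie at the top counts as failure). Zero-variance
#' maps are excluded with a flag.
#'
#' @param followup_maps `[n_followup, n_channels, nv]` array of flattened
#'   deviation maps (mask voxels only).
#' @param candidate_maps `[n_candidates, n_channels, nv]` array.
#' @param self_index Integer vector: for each follow-up row, the candidate row
#'   holding that subject's first-timepoint map.
#' @param channels Channels to score (default all).
#' @return Object of class `fingerprint_result`: per channel, the correlation
#'   matrix, self ranks, identification count and rate, excluded subjects.
#' @export
fingerprint_identify <- function(followup_maps, candidate_maps, self_index,
                                 channels = NULL) {
  nf <- dim(followup_maps)[1]; nc <- dim(candidate_maps)[1]
  ncha <- dim(followup_maps)[2]
  channels <- channels %||% seq_len(ncha)
  if (length(self_index) != nf) stop_arg("self_index must have one entry per follow-up")
  if (any(self_index < 1 | self_index > nc)) stop_arg("self_index out of range")
  res <- list()
  for (ch in channels) {
    Fm <- matrix(followup_maps[, ch, ], nrow = nf)
    Cm <- matrix(candidate_maps[, ch, ], nrow = nc)
    excl <- which(apply(Fm, 1, stats::sd) == 0)
    R <- suppressWarnings(stats::cor(t(Fm), t(Cm)))   # nf x nc
    ranks <- rep(NA_integer_, nf); identified <- rep(NA, nf)
    for (i in seq_len(nf)) {
      if (i %in% excl || stats::sd(Cm[self_index[i], ]) == 0) next
      r <- R[i, ]
      self_r <- r[self_index[i]]
      others <- r[-self_index[i]]
      ranks[i] <- 1L + sum(others >= self_r, na.rm = TRUE)  # pessimistic ties
      identified[i] <- ranks[i] == 1L
    }
    ok <- !is.na(identified)
    res[[as.character(ch)]] <- list(correlation = R, rank = ranks,
                                    identified = identified,
                                    n_identified = sum(identified[ok]),
                                    n_scored = sum(ok),
                                    rate = sum(identified[ok]) / max(sum(ok), 1),
                                    excluded = excl)
  }
  structure(res, class = "fingerprint_result")
}

#' Relation between inter-scan interval and self-similarity
#'
#' Pearson correlation of the self-correlation (similarity of a subject's two
#' deviation maps) against the interval between scans. Both sign conventions
#' are reported: `r` on the raw interval and `r_similarity_decay = -r` (longer
#' interval, lower similarity gives positive decay).
#'
#' @param intervals_weeks Numeric vector of inter-scan intervals.
#' @param self_correlations Matching self-similarity values.
#' @return List with `r`, `p.value`, `r_similarity_decay`, `n` (`r` is NA when
#'   either input is constant).
#' @export
interval_similarity <- function(intervals_weeks, self_correlations) {
  if (length(intervals_weeks) < 5) stop_arg("need at least 5 pairs")
  if (length(intervals_weeks) != length(self_correlations))
    stop_arg("inputs must be the same length")
  if (stats::sd(intervals_weeks) == 0 || stats::sd(self_correlations) == 0)
    return(list(r = NA_real_, p.value = NA_real_, r_similarity_decay = NA_real_,
                n = length(intervals_weeks)))
  ct <- stats::cor.test(intervals_weeks, self_correlations)
  list(r = unname(ct$estimate), p.value = ct$p.value,
       r_similarity_decay = -unname(ct$estimate), n = length(intervals_weeks))
}
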