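# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays well inside its budget.

fix_design <- function(n, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  set.seed(seed)
  cbind(pma = runif(n, 28, 45), ga = runif(n, 24, 42), sex = rbinom(n, 1, 0.5))
}

fix_kernel <- function() kernel_params(0.3, 1.2, 1.5, 0.4)

fix_coreg <- function(m = 3, R = 2, seed = 2) {
  set.seed(seed)
  coreg_params(matrix(rnorm(m * R, 0, 0.6), m, R), runif(m, 0.1, 0.5))
}

# Dense LML oracle: explicit inverse + log-determinant on the stacked vector.
oracle_lml <- function(X, Y, kernel, coreg) {
  K <- icm_covariance(kernel, coreg, X, X, include_white = TRUE)
  y <- as.numeric(Y)
  n <- length(y)
  as.numeric(-0.5 * t(y) %*% solve(K, y) -
               0.5 * determinant(K, logarithm = TRUE)$modulus - 0.5 * n * log(2 * pi))
}

# Textbook closed-form posterior oracle for output i at query points Xn.
oracle_predict <- function(X, Y, kernel, coreg, Xn, i, include_noise = FALSE) {
  B <- coreg_matrix(coreg)
  m <- ncol(Y)
  K <- icm_covariance(kernel, coreg, X, X, include_white = TRUE)
  Klat <- kernel_matrix(kernel, X, Xn)
  Kstar <- do.call(rbind, lapply(seq_len(m), function(c) B[c, i] * Klat))
  y <- as.numeric(Y)
  mu <- drop(crossprod(Kstar, solve(K, y)))
  kss <- kernel$linear_variance * rowSums(Xn^2) + kernel$rbf_variance
  v <- B[i, i] * kss - colSums(solve(K, Kstar) * Kstar)
  if (include_noise) v <- v + B[i, i] * kernel$white_variance
  list(mean = mu, var = v)
}

fix_small_cohort <- function(n = 30, gs = c(5, 5, 5), noise_sd = 1,
                             subject_effect_sd = 0.5, seed = 3, n_labels = 2) {
  generate_cohort(n, tissue_label_map(gs, n_labels = n_labels),
                  noise_sd = noise_sd, subject_effect_sd = subject_effect_sd,
                  seed = seed)
}
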