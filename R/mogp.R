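# Multi-output GP (intrinsic coregionalization model) over a (PMA, GA, sex)
# design. With the coupled noise model the joint covariance of the stacked
# outputs is exactly Kronecker, K = B %x% C with C = k_lin + k_rbf + sigma_w^2 I,
# so the log marginal likelihood and its gradients are computed from the
# eigendecompositions of B (m x m) and C (n x n) instead of a dense nm x nm
# Cholesky. The dense route is kept for the independent-noise option and as
# the oracle path in tests.

EIG_FLOOR <- 1e-10

# Per-design precomputations shared across likelihood evaluations.
mogp_precompute <- function(X) {
  X <- as.matrix(X)
  list(X = X, n = nrow(X), L = tcrossprod(X),
       D = lapply(seq_len(ncol(X)), function(d) outer(X[, d], X[, d], "-")^2))
}

# Input-kernel matrix and RBF factor from precomputations.
kernel_from_precomp <- function(pre, lin, rbf, ell, white) {
  if (length(ell) == 1L) ell <- rep(ell, length(pre$D))
  D2 <- Reduce(`+`, Map(function(Dd, e) Dd / e^2, pre$D, as.list(ell)))
  E <- exp(-0.5 * D2)
  list(C = lin * pre$L + rbf * E + diag(white, pre$n), E = E)
}

# theta layout: log lin, log rbf, log ell (1 or 3), log white, W (m*R), log kappa (m)
theta_pack <- function(kernel, coreg) {
  c(log(max(kernel$linear_variance, 1e-12)), log(max(kernel$rbf_variance, 1e-12)),
    log(kernel$rbf_lengthscale), log(max(kernel$white_variance, 1e-8)),
    as.numeric(coreg$W), log(pmax(coreg$kappa, 1e-8)))
}

theta_unpack <- function(theta, m, R, nl) {
  lin <- exp(theta[1]); rbf <- exp(theta[2]); ell <- exp(theta[3:(2 + nl)])
  white <- exp(theta[3 + nl])
  W <- matrix(theta[(4 + nl):(3 + nl + m * R)], m, R)
  kappa <- exp(theta[(4 + nl + m * R):(3 + nl + m * R + m)])
  list(kernel = kernel_params(lin, rbf, ell, white), coreg = coreg_params(W, kappa))
}

# Cholesky with a jitter ladder (1e-8 -> 1e-4 relative to mean diagonal).
chol_jitter <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  jit <- 1e-8 * mean(diag(M))
  while (is.null(ch) && jit <= 1e-4 * mean(diag(M))) {
    ch <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    jit <- jit * 10
  }
  if (is.null(ch))
    stop("Cholesky failed after jitter ladder 1e-8..1e-4; covariance not positive definite",
         call. = FALSE)
  ch
}

# Log marginal likelihood + gradient under the Kronecker (coupled-noise) model,
# K = B %x% C, so K^-1 = B^-1 %x% C^-1 and only an n x n Cholesky is needed.
# Gradients use alpha = C^-1 Y B^-1 in matrix form; for any symmetric input-
# kernel direction dC, dLML = 0.5 * (sum(A * (dC %*% A %*% B)) - m * sum(Cinv * dC)),
# and for output directions dB the carrier is GB = 0.5 * (A' Y Binv - n * Binv).
# Returns list(lml, grad) on the log-parameter scale.
kron_lml_grad <- function(theta, pre, Y, m, R, nl, want_grad = TRUE) {
  p <- theta_unpack(theta, m, R, nl)
  kp <- p$kernel
  kc <- kernel_from_precomp(pre, kp$linear_variance, kp$rbf_variance,
                            kp$rbf_lengthscale, kp$white_variance)
  B <- coreg_matrix(p$coreg)
  n <- pre$n
  chC <- chol_jitter(kc$C)
  chB <- chol_jitter(B)
  ldC <- 2 * sum(log(diag(chC))); ldB <- 2 * sum(log(diag(chB)))
  Binv <- chol2inv(chB)
  CiY <- backsolve(chC, forwardsolve(t(chC), Y))
  A <- CiY %*% Binv                                # alpha in matrix form
  lml <- -0.5 * sum(Y * A) - 0.5 * (m * ldC + n * ldB) - 0.5 * n * m * log(2 * pi)
  if (!want_grad) return(list(lml = lml, kernel = kp, coreg = p$coreg))
  Cinv <- chol2inv(chC)
  H <- A %*% B                                     # equals C^-1 Y, n x m
  g_dir <- function(dC)                            # dC symmetric n x n
    0.5 * (sum(A * (dC %*% H)) - m * sum(Cinv * dC))
  g_lin <- g_dir(pre$L) * kp$linear_variance
  Evar <- kp$rbf_variance * kc$E
  g_rbf <- g_dir(Evar)
  ell <- if (nl == 1L) rep(kp$rbf_lengthscale, length(pre$D)) else kp$rbf_lengthscale
  if (nl == 1L) {
    D2 <- Reduce(`+`, pre$D) / ell[1]^2
    g_ell <- g_dir(Evar * D2)
  } else {
    g_ell <- vapply(seq_len(nl), function(d)
      g_dir(Evar * pre$D[[d]] / ell[d]^2), numeric(1))
  }
  g_white <- 0.5 * (sum(A * H) - m * sum(diag(Cinv))) * kp$white_variance
  GB <- 0.5 * (crossprod(A, Y) %*% Binv - n * Binv)
  g_W <- 2 * GB %*% p$coreg$W
  g_kappa <- diag(GB) * p$coreg$kappa
  list(lml = lml, grad = c(g_lin, g_rbf, g_ell, g_white, as.numeric(g_W), g_kappa),
       kernel = kp, coreg = p$coreg)
}

# Dense-route LML used for the independent-noise model (and small problems).
dense_lml <- function(kernel, coreg, X, Y, noise, per_output_noise = NULL) {
  m <- ncol(Y); n <- nrow(Y)
  K <- icm_covariance(kernel, coreg, X, X, include_white = TRUE, noise = noise,
                      per_output_noise = per_output_noise)
  y <- as.numeric(Y)  # output-major stacking matches icm_covariance grid mode
  ch <- tryCatch(chol(K), error = function(e) NULL)
  jit <- 1e-8
  while (is.null(ch) && jit <= 1e-4) {
    ch <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    jit <- jit * 10
  }
  if (is.null(ch))
    stop("Cholesky failed after jitter ladder 1e-8..1e-4; covariance not PD", call. = FALSE)
  a <- backsolve(ch, forwardsolve(t(ch), y))
  -0.5 * sum(y * a) - sum(log(diag(ch))) - 0.5 * n * m * log(2 * pi)
}

#' Log marginal likelihood of a multi-output GP
#'
#' Computes \eqn{-\frac12 y^T K^{-1} y - \frac12 \log|K| - \frac{nm}{2}\log 2\pi}
#' on the stacked (output-major) observation vector. No standardization is
#' applied; inputs and outputs are used as given.
#'
#' @param X `n x d` design matrix.
#' @param Y `n x m` output matrix.
#' @param kernel,coreg Parameter objects (see [kernel_params()], [coreg_params()]).
#' @param noise `"coupled"` or `"independent"` white-noise model.
#' @param per_output_noise Optional per-output noise variances (independent model).
#' @return Scalar log marginal likelihood.
#' @export
mogp_lml <- function(X, Y, kernel, coreg, noise = c("coupled", "independent"),
                     per_output_noise = NULL) {
  noise <- match.arg(noise)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (noise == "independent")
    return(dense_lml(kernel, coreg, X, Y, noise, per_output_noise))
  n <- nrow(Y); m <- ncol(Y)
  C <- kernel_matrix(kernel, X, include_white = TRUE)
  B <- coreg_matrix(coreg)
  chC <- chol_jitter(C); chB <- chol_jitter(B)
  A <- backsolve(chC, forwardsolve(t(chC), Y)) %*% chol2inv(chB)
  -0.5 * sum(Y * A) - 0.5 * (m * 2 * sum(log(diag(chC))) +
                               n * 2 * sum(log(diag(chB)))) -
    0.5 * n * m * log(2 * pi)
}

default_init <- function(m, R) {
  list(kernel = kernel_params(0.1, 0.5, 1, 0.3),
       coreg = coreg_params(matrix(sqrt(0.5 / R), m, R), rep(0.5, m)))
}

#' Fit a multi-output GP by maximizing log marginal likelihood
#'
#' Quasi-Newton (L-BFGS-B) optimization over log-transformed positive
#' parameters with multiple seeded restarts; the restart with the highest log
#' marginal likelihood wins (ties broken by lowest restart index). PMA and GA
#' (columns 1-2) are z-scored with training statistics and each output column
#' is standardized; predictions are returned in original units.
#'
#' @param X `n x 3` design matrix (pma_weeks, ga_weeks, sex).
#' @param Y `n x m` output matrix (m = 5 channels for voxel models, 1 for
#'   affine-element models).
#' @param init Optional list with `kernel` and `coreg` initial values.
#' @param n_restarts Number of optimizer restarts (first uses `init`).
#' @param seed Integer seed controlling restart jitter.
#' @param rank Coregionalization rank R (W is `m x R`).
#' @param noise `"coupled"` (default) or `"independent"` white-noise model.
#' @param ard Use one lengthscale per input instead of a shared one.
#' @param standardize Standardize inputs/outputs (default `TRUE`).
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param allow_constant Accept constant output columns (centred, unit scale)
#'   instead of raising; used for shape elements that may legitimately be
#'   constant. Voxel models keep the error and exclude such voxels upstream.
#' @return An object of class `mogp_fit`.
#' @export
mogp_fit <- function(X, Y, init = NULL, n_restarts = 3, seed = 1, rank = 2,
                     noise = c("coupled", "independent"), ard = FALSE,
                     standardize = TRUE, maxit = 100, allow_constant = FALSE) {
  noise <- match.arg(noise)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(Y)
  if (n < 3) stop_arg("at least 3 training subjects required, got %d", n)
  if (nrow(Y) != n) stop_arg("X and Y row counts differ")
  rank <- min(rank, m)
  if (standardize) {
    x_center <- c(mean(X[, 1]), mean(X[, 2]), 0)
    x_scale <- c(max(stats::sd(X[, 1]), 1e-8), max(stats::sd(X[, 2]), 1e-8), 1)
    y_center <- colMeans(Y)
    y_sd <- apply(Y, 2, stats::sd)
    if (any(y_sd == 0) && !allow_constant)
      stop_arg("degenerate (constant) output column; exclude the voxel upstream")
    y_scale <- ifelse(y_sd == 0, 1, y_sd)  # constant column -> centred zeros
  } else {
    x_center <- rep(0, ncol(X)); x_scale <- rep(1, ncol(X))
    y_center <- rep(0, m); y_scale <- rep(1, m)
  }
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  Ys <- sweep(sweep(Y, 2, y_center), 2, y_scale, "/")
  nl <- if (ard) ncol(X) else 1L
  pre <- mogp_precompute(Xs)
  if (is.null(init)) init <- default_init(m, rank)
  if (length(init$kernel$rbf_lengthscale) != nl)
    init$kernel$rbf_lengthscale <- rep(init$kernel$rbf_lengthscale[1], nl)
  theta0 <- theta_pack(init$kernel, init$coreg)
  memo <- new.env(parent = emptyenv())  # fn and gr are called at the same point
  objective <- function(th) {
    if (!is.null(memo$th) && identical(th, memo$th)) return(memo$res)
    r <- tryCatch(kron_lml_grad(th, pre, Ys, m, rank, nl),
                  error = function(e) NULL)
    res <- if (is.null(r) || !is.finite(r$lml))
      list(value = 1e10, grad = rep(0, length(th)))
    else list(value = -r$lml, grad = -r$grad)
    memo$th <- th; memo$res <- res
    res
  }
  fn <- function(th) objective(th)$value
  gr <- function(th) objective(th)$grad
  lml_of <- function(th) {
    if (noise == "coupled")
      kron_lml_grad(th, pre, Ys, m, rank, nl, want_grad = FALSE)$lml
    else {
      p <- theta_unpack(th, m, rank, nl)
      dense_lml(p$kernel, p$coreg, Xs, Ys, noise)
    }
  }
  lower <- rep(-Inf, length(theta0)); upper <- rep(Inf, length(theta0))
  pos_idx <- c(1:2, 3:(2 + nl), 3 + nl,
               (4 + nl + m * rank):(3 + nl + m * rank + m))
  lower[pos_idx] <- log(1e-8); upper[pos_idx] <- log(1e6)
  best <- NULL; best_lml <- -Inf; n_fail <- 0
  for (r in seq_len(max(1, n_restarts))) {
    th_init <- if (r == 1) theta0 else with_seed(derive_seed(seed, r), {
      th <- theta0
      th[pos_idx] <- th[pos_idx] + stats::rnorm(length(pos_idx), 0, 0.5)
      wseg <- (4 + nl):(3 + nl + m * rank)
      th[wseg] <- stats::rnorm(length(wseg), 0, sqrt(0.5 / rank))
      th
    })
    res <- if (noise == "coupled") {
      tryCatch(stats::optim(th_init, fn, gr, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = maxit, factr = 1e9)),
               error = function(e) NULL)
    } else {
      # independent noise: dense likelihood, numerical gradients
      fn_d <- function(th) {
        v <- tryCatch(-lml_of(th), error = function(e) 1e10)
        if (!is.finite(v)) 1e10 else v
      }
      tryCatch(stats::optim(th_init, fn_d, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = maxit, factr = 1e9)),
               error = function(e) NULL)
    }
    if (is.null(res)) { n_fail <- n_fail + 1; next }
    cand_lml <- tryCatch(lml_of(res$par), error = function(e) -Inf)
    if (is.finite(cand_lml) && cand_lml > best_lml) {
      best <- res; best_lml <- cand_lml
    }
  }
  if (is.null(best)) {
    init_lml <- tryCatch(lml_of(theta0), error = function(e) -Inf)
    err <- simpleError("all optimizer restarts failed")
    err$partial <- list(theta = theta0, lml = init_lml)
    stop(err)
  }
  p <- theta_unpack(best$par, m, rank, nl)
  fit <- structure(list(kernel = p$kernel, coreg = p$coreg, noise = noise,
                        X = X, Y = Y, Xs = Xs, Ys = Ys,
                        x_center = x_center, x_scale = x_scale,
                        y_center = y_center, y_scale = y_scale,
                        lml = best_lml, n_outputs = m, rank = rank,
                        convergence = best$convergence, n_failed_restarts = n_fail),
                   class = "mogp_fit")
  fit
}

# Posterior cache: eigendecompositions and alpha for prediction.
mogp_cache <- function(fit) {
  pre <- mogp_precompute(fit$Xs)
  kc <- kernel_from_precomp(pre, fit$kernel$linear_variance, fit$kernel$rbf_variance,
                            fit$kernel$rbf_lengthscale, fit$kernel$white_variance)
  B <- coreg_matrix(fit$coreg)
  if (fit$noise == "independent") {
    K <- icm_covariance(fit$kernel, fit$coreg, fit$Xs, fit$Xs,
                        include_white = TRUE, noise = "independent")
    ch <- chol(K + diag(1e-10, nrow(K)))
    alpha <- backsolve(ch, forwardsolve(t(ch), as.numeric(fit$Ys)))
    return(list(B = B, chol = ch, alpha = alpha, dense = TRUE))
  }
  chC <- chol_jitter(kc$C); chB <- chol_jitter(B)
  Binv <- chol2inv(chB)
  A <- backsolve(chC, forwardsolve(t(chC), fit$Ys)) %*% Binv
  list(B = B, chC = chC, Binv = Binv, A = A, dense = FALSE)
}

#' Posterior predictive mean and standard deviation
#'
#' @param object A fitted `mogp_fit`.
#' @param X_new `m_new x 3` matrix of query covariates (original units).
#' @param output_index Outputs to predict (default all).
#' @param include_noise Add the output's white-noise share to the predictive
#'   variance (the variant used for deviation Z-scores).
#' @param ... Unused.
#' @return List with `mean` and `sd`, each `m_new x length(output_index)`,
#'   in original (de-standardized) units.
#' @export
predict.mogp_fit <- function(object, X_new, output_index = NULL,
                             include_noise = TRUE, ...) {
  fit <- object
  X_new <- matrix(as.numeric(X_new), ncol = length(fit$x_center))
  output_index <- output_index %||% seq_len(fit$n_outputs)
  Xn <- sweep(sweep(X_new, 2, fit$x_center), 2, fit$x_scale, "/")
  ca <- mogp_cache(fit)
  Kx <- kernel_matrix(fit$kernel, fit$Xs, Xn, include_white = FALSE)  # n x m_new
  kss <- fit$kernel$linear_variance * rowSums(Xn^2) + fit$kernel$rbf_variance
  B <- ca$B
  mu <- matrix(NA_real_, nrow(Xn), length(output_index))
  va <- matrix(NA_real_, nrow(Xn), length(output_index))
  if (ca$dense) {
    n <- nrow(fit$Xs); m <- fit$n_outputs
    for (q in seq_along(output_index)) {
      i <- output_index[q]
      Kstar <- do.call(rbind, lapply(seq_len(m), function(c) B[c, i] * Kx))
      mu[, q] <- crossprod(Kstar, ca$alpha)
      v <- forwardsolve(t(ca$chol), Kstar)
      va[, q] <- pmax(B[i, i] * kss - colSums(v^2), 1e-12)
    }
  } else {
    # (B[,i] %x% k*)' K^-1 (B[,i] %x% k*) factorizes over the two Kroneckers
    sV <- colSums(forwardsolve(t(ca$chC), Kx)^2)   # k*' C^-1 k* per query
    M <- ca$A %*% B
    for (q in seq_along(output_index)) {
      i <- output_index[q]
      bq <- as.numeric(crossprod(B[, i], ca$Binv %*% B[, i]))
      mu[, q] <- crossprod(Kx, M[, i])
      va[, q] <- pmax(B[i, i] * kss - sV * bq, 1e-12)
    }
  }
  if (include_noise) {
    for (q in seq_along(output_index)) {
      i <- output_index[q]
      va[, q] <- va[, q] + if (fit$noise == "coupled")
        B[i, i] * fit$kernel$white_variance else fit$kernel$white_variance
    }
  }
  ys <- fit$y_scale[output_index]; yc <- fit$y_center[output_index]
  list(mean = sweep(sweep(mu, 2, ys, "*"), 2, yc, "+"),
       sd = sweep(sqrt(va), 2, ys, "*"))
}
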