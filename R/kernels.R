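#' Kernel hyperparameters for the voxelwise GP
#'
#' The input kernel is the sum of a linear, a squared-exponential (RBF) and a
#' white-noise term over the standardized design inputs (PMA, GA, sex):
#' \deqn{k(x,x') = \sigma^2_{lin}\langle x,x'\rangle +
#'   \sigma^2_{rbf}\exp(-\tfrac12\|(x-x')/\ell\|^2) + \sigma^2_w\delta_{xx'}}
#'
#' @param linear_variance Non-negative variance of the linear term.
#' @param rbf_variance Non-negative variance of the RBF term.
#' @param rbf_lengthscale Positive lengthscale; scalar (isotropic, default) or
#'   a 3-vector for ARD over the three inputs.
#' @param white_variance Positive white-noise variance (floored at 1e-8).
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(linear_variance = 0.1, rbf_variance = 1,
                          rbf_lengthscale = 1, white_variance = 0.1) {
  if (any(!is.finite(c(linear_variance, rbf_variance, rbf_lengthscale, white_variance))))
    stop_arg("kernel parameters must be finite")
  if (linear_variance < 0 || rbf_variance < 0)
    stop_arg("kernel variances must be non-negative")
  if (any(rbf_lengthscale <= 0)) stop_arg("rbf_lengthscale must be positive")
  if (!length(rbf_lengthscale) %in% c(1L, 3L))
    stop_arg("rbf_lengthscale must be scalar or length 3")
  structure(list(linear_variance = linear_variance,
                 rbf_variance = rbf_variance,
                 rbf_lengthscale = rbf_lengthscale,
                 white_variance = max(white_variance, 1e-8)),
            class = "kernel_params")
}

#' Coregionalization parameters for the intrinsic coregionalization model
#'
#' The output-mixing matrix is \eqn{B = WW^T + diag(\kappa)}; the joint
#' covariance over (input, output) pairs is \eqn{B_{ij} k(x, x')}.
#'
#' @param W `n_outputs x rank` mixing-weight matrix.
#' @param kappa Non-negative per-output variance vector (length `n_outputs`).
#' @return An object of class `coreg_params`.
#' @export
coreg_params <- function(W, kappa) {
  W <- as.matrix(W)
  if (length(kappa) != nrow(W)) stop_arg("kappa length must match nrow(W)")
  if (any(kappa < 0)) stop_arg("kappa must be non-negative")
  structure(list(W = W, kappa = as.numeric(kappa)), class = "coreg_params")
}

#' Assemble the output-mixing matrix B
#' @param coreg A `coreg_params` object.
#' @return Symmetric PSD matrix `W %*% t(W) + diag(kappa)`.
#' @export
coreg_matrix <- function(coreg) {
  tcrossprod(coreg$W) + diag(coreg$kappa, nrow(coreg$W))
}

# Squared Euclidean distance matrix between rows, after lengthscale division.
sqdist <- function(X1, X2, ell) {
  if (length(ell) == 1L) ell <- rep(ell, ncol(X1))
  X1 <- sweep(X1, 2, ell, "/"); X2 <- sweep(X2, 2, ell, "/")
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  pmax(d2, 0)
}

#' Evaluate the summed kernel between two sets of inputs
#'
#' @param params A `kernel_params` object.
#' @param X1,X2 Design matrices (`n x 3`, `m x 3`).
#' @param include_white If `TRUE` and `X1`, `X2` describe the same training
#'   block (`n == m`), adds `white_variance` on the diagonal. White noise is
#'   tied to the training index, never to cross-covariances.
#' @return `n x m` covariance matrix.
#' @export
kernel_matrix <- function(params, X1, X2 = X1, include_white = FALSE) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (any(!is.finite(X1)) || any(!is.finite(X2)))
    stop_arg("kernel inputs must be finite")
  K <- params$linear_variance * tcrossprod(X1, X2) +
    params$rbf_variance * exp(-0.5 * sqdist(X1, X2, params$rbf_lengthscale))
  if (include_white) {
    if (nrow(X1) != nrow(X2))
      stop_arg("include_white requires X1 and X2 to be the same training block")
    K <- K + diag(params$white_variance, nrow(X1))
  }
  K
}

#' Full ICM covariance over (input, output-index) pairs
#'
#' Entry ((x, i), (x', j)) is `B[i, j] * k(x, x')`. When `out1`/`out2` are
#' `NULL` the matrix covers all outputs in output-major order, i.e. the
#' Kronecker product `B %x% k(X1, X2)`. With the default coupled noise model
#' the white term is shared through B (`B_ij * sigma_w^2` on matching input
#' points); with independent noise it attaches only to matching
#' (point, output) pairs.
#'
#' @param kernel A `kernel_params` object.
#' @param coreg A `coreg_params` object.
#' @param X1,X2 Design matrices of input points (`n x 3`, `m x 3`).
#' @param out1,out2 Optional integer output indices (one per row of X); `NULL`
#'   expands every point over all outputs, output-major.
#' @param include_white Add the white term on the training diagonal block
#'   (requires X1 and X2 to be the same block).
#' @param noise `"coupled"` (white shared through B, default) or
#'   `"independent"` (per-output white).
#' @param per_output_noise Noise variances for `noise = "independent"`;
#'   defaults to `white_variance` for every output.
#' @return Covariance matrix over all (point, output) pairs.
#' @export
icm_covariance <- function(kernel, coreg, X1, X2 = X1, out1 = NULL, out2 = NULL,
                           include_white = FALSE, noise = c("coupled", "independent"),
                           per_output_noise = NULL) {
  noise <- match.arg(noise)
  B <- coreg_matrix(coreg)
  m <- nrow(B)
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n1 <- nrow(X1); n2 <- nrow(X2)
  if (is.null(out1)) { idx1 <- rep(seq_len(n1), times = m); out1 <- rep(seq_len(m), each = n1) }
  else idx1 <- seq_len(n1)
  if (is.null(out2)) { idx2 <- rep(seq_len(n2), times = m); out2 <- rep(seq_len(m), each = n2) }
  else idx2 <- seq_len(n2)
  if (any(out1 < 1 | out1 > m) || any(out2 < 1 | out2 > m))
    stop_arg("output index out of range 1..%d", m)
  Klat <- kernel_matrix(kernel, X1, X2, include_white = FALSE)
  K <- B[cbind(rep(out1, times = length(out2)), rep(out2, each = length(out1)))] *
    Klat[cbind(rep(idx1, times = length(idx2)), rep(idx2, each = length(idx1)))]
  K <- matrix(K, length(out1), length(out2))
  if (include_white) {
    if (n1 != n2) stop_arg("include_white requires matching training blocks")
    same_pt <- outer(idx1, idx2, "==")
    if (noise == "coupled") {
      Bpair <- matrix(B[cbind(rep(out1, times = length(out2)),
                              rep(out2, each = length(out1)))],
                      length(out1), length(out2))
      K <- K + Bpair * kernel$white_variance * same_pt
    } else {
      pon <- per_output_noise %||% rep(kernel$white_variance, m)
      K <- K + (outer(out1, out2, "==") * same_pt) * pon[out1]
    }
  }
  K
}
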