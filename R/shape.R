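# Global shape model: per-subject affine transforms are decomposed into
# stretch and shear; the six elements are modelled separately with
# single-output GPRs sharing the voxel models' design matrix and fold scheme.
# Rotation and translation are carried through but never modelled.

#' Decompose the linear part of an affine into rotation, stretch and shear
#'
#' QR-style decomposition `A = R U` with R a proper rotation and U upper
#' triangular with positive diagonal (graphics convention): stretch is
#' `diag(U)` and shear the dimensionless ratios `(U12/U11, U13/U11, U23/U22)`.
#'
#' @param linear_part 3x3 matrix with positive determinant.
#' @param method `"qr"` (default) or `"polar"` (sensitivity variant; stretch
#'   and shear then come from the symmetric factor's triangular reduction).
#' @return List with `rotation`, `stretch`, `shear`, `translation` (zeros;
#'   carried by the caller) of class `affine_decomposition`.
#' @export
decompose_affine <- function(linear_part, method = c("qr", "polar")) {
  method <- match.arg(method)
  A <- as.matrix(linear_part)
  if (!all(dim(A) == c(3, 3))) stop_arg("linear_part must be 3x3")
  d <- det(A)
  if (!is.finite(d) || abs(d) < 1e-12) stop_arg("singular linear part")
  if (d < 0) stop_arg("reflecting transform (negative determinant) not supported")
  if (method == "polar") {
    s <- svd(A)
    R <- s$u %*% t(s$v)                 # closest rotation (A = R P)
    U <- s$v %*% diag(s$d) %*% t(s$v)   # symmetric positive-definite factor
  } else {
    qrd <- qr(A)
    Q <- qr.Q(qrd); Um <- qr.R(qrd)
    sgn <- sign(diag(Um)); sgn[sgn == 0] <- 1
    S <- diag(sgn)
    Q <- Q %*% S; U <- S %*% Um         # A = Q U, U upper tri, diag > 0
    R <- Q
  }
  if (det(R) < 0) stop_arg("decomposition produced an improper rotation")
  structure(list(rotation = R, stretch = diag(U),
                 shear = c(U[1, 2] / U[1, 1], U[1, 3] / U[1, 1], U[2, 3] / U[2, 2]),
                 translation = c(0, 0, 0), factor = U, method = method),
            class = "affine_decomposition")
}

#' Recompose the linear part from a decomposition
#'
#' Uses the stored shape factor when present (exact for both dialects);
#' otherwise rebuilds the upper-triangular factor from stretch and shear.
#'
#' @param dec An `affine_decomposition`.
#' @return 3x3 matrix `rotation %*% factor`.
#' @export
recompose_affine <- function(dec) {
  U <- dec$factor
  if (is.null(U)) {
    U <- diag(dec$stretch)
    U[1, 2] <- dec$shear[1] * U[1, 1]
    U[1, 3] <- dec$shear[2] * U[1, 1]
    U[2, 3] <- dec$shear[3] * U[2, 2]
  }
  dec$rotation %*% U
}

#' Fit growth models for the six affine shape elements
#'
#' Decomposes every subject's affine and fits each of the six elements
#' (3 stretches, 3 shears) in its own single-output GP with the same
#' (PMA, GA, sex) design and kernel family as the voxel models.
#'
#' @param affines List of 3x4 affine matrices (one per subject).
#' @param covariates Covariate table aligned with `affines`.
#' @param n_restarts,seed,maxit Passed to [mogp_fit()].
#' @return List of 6 `mogp_fit` objects named
#'   `stretch_x/y/z`, `shear_xy/xz/yz`, class `shape_growth_fit`.
#' @export
fit_shape_growth <- function(affines, covariates, n_restarts = 2, seed = 1,
                             maxit = 100) {
  if (length(affines) < 10) stop_arg("at least 10 subjects required")
  validate_covariates(covariates)
  el <- t(vapply(affines, function(a) {
    d <- decompose_affine(a[, 1:3])
    c(d$stretch, d$shear)
  }, numeric(6)))
  colnames(el) <- c("stretch_x", "stretch_y", "stretch_z",
                    "shear_xy", "shear_xz", "shear_yz")
  X <- design_matrix(covariates)
  fits <- lapply(seq_len(6), function(j)
    mogp_fit(X, el[, j, drop = FALSE], rank = 1, n_restarts = n_restarts,
             seed = derive_seed(seed, j), maxit = maxit, allow_constant = TRUE))
  names(fits) <- colnames(el)
  structure(list(fits = fits, elements = el), class = "shape_growth_fit")
}

#' Predict the six shape elements at given covariates
#' @param shape A `shape_growth_fit`.
#' @param covariates One covariate row.
#' @param include_noise Include noise in the predictive SD.
#' @return List with `mean` and `sd`, named 6-vectors.
#' @export
predict_shape <- function(shape, covariates, include_noise = FALSE) {
  X <- cbind(covariates$pma_weeks, covariates$ga_weeks, covariates$sex)
  res <- lapply(shape$fits, function(f) predict(f, X, include_noise = include_noise))
  list(mean = vapply(res, function(r) r$mean[1, 1], numeric(1)),
       sd = vapply(res, function(r) r$sd[1, 1], numeric(1)))
}

#' Assemble a 3x4 affine from predicted stretch/shear
#' @param elements Named 6-vector as returned by [predict_shape()]`$mean`.
#' @return 3x4 affine (rotation = identity, translation = 0).
#' @export
affine_from_elements <- function(elements) {
  dec <- structure(list(rotation = diag(3),
                        stretch = elements[1:3], shear = elements[4:6]),
                   class = "affine_decomposition")
  cbind(recompose_affine(dec), c(0, 0, 0))
}

# Trilinear interpolation of a 3-D volume at fractional 1-based coordinates.
# Points outside the grid return `fill`.
trilinear <- function(vol, pts, fill = 0) {
  gs <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  out <- rep(fill, nrow(pts))
  ok <- x >= 1 & x <= gs[1] & y >= 1 & y <= gs[2] & z >= 1 & z <= gs[3]
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), gs[1] - 1); y0 <- pmin(floor(y), gs[2] - 1)
  z0 <- pmin(floor(z), gs[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * fx + (1 - dx) * (1 - fx)) *
      (dy * fy + (1 - dy) * (1 - fy)) *
      (dz * fz + (1 - dz) * (1 - fz))
    val <- val + w * vol[cbind(x0 + dx, y0 + dy, z0 + dz)]
  }
  out[ok] <- val
  out
}

#' Render a template-space prediction into native space
#'
#' For each native voxel y the template sample point is
#' `x = T^{-1} y + d(T^{-1} y)`: the predicted affine `T` maps template to
#' native coordinates and the displacement field `d` (template-grid, voxel
#' units) is applied before the affine in the template->native composition.
#' The volume is pulled back by trilinear resampling; out-of-field voxels are
#' zero.
#'
#' @param volume 3-D template-space array (e.g. a predicted intensity channel).
#' @param affine 3x4 or 3x3 matrix mapping template to native voxel
#'   coordinates (0-based convention internally; callers pass plain matrices).
#' @param displacement Optional `[3, nx, ny, nz]` field of template-space
#'   offsets in voxel units; `NULL` means zero.
#' @param out_shape Native grid shape (defaults to `dim(volume)`).
#' @return Native-space array of shape `out_shape`.
#' @export
render_native <- function(volume, affine, displacement = NULL,
                          out_shape = dim(volume)) {
  A <- as.matrix(affine)
  lin <- A[, 1:3, drop = FALSE]
  tr <- if (ncol(A) == 4) A[, 4] else c(0, 0, 0)
  if (abs(det(lin)) < 1e-12) stop_arg("predicted affine is not invertible")
  lin_inv <- solve(lin)
  g <- as.matrix(expand.grid(x = seq_len(out_shape[1]), y = seq_len(out_shape[2]),
                             z = seq_len(out_shape[3])))
  # work 0-based so that scaling is about the grid origin
  xt <- t(lin_inv %*% (t(g) - 1 - tr)) + 1
  if (!is.null(displacement)) {
    d <- vapply(1:3, function(k) trilinear(displacement[k, , , ], xt), numeric(nrow(xt)))
    xt <- xt + d
  }
  array(trilinear(volume, xt), out_shape)
}
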