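test_that("log marginal likelihood matches the scalar Gaussian density", {
  # single point, single output: lml = log N(y | 0, k(x,x))
  kp <- kernel_params(0, 2, 1, 0.5)  # k(0,0) = 2 + 0.5
  cg <- coreg_params(matrix(1, 1, 1), 0)
  v <- 2.5; y <- 2
  expect_equal(mogp_lml(matrix(0, 1, 3), matrix(y, 1, 1), kp, cg),
               -0.5 * y^2 / v - 0.5 * log(2 * pi * v), tolerance = 1e-10)
  # zero outputs: only the log-determinant terms remain
  X <- fix_design(4)
  cg3 <- fix_coreg(3, 2)
  K <- icm_covariance(kp, cg3, X, X, include_white = TRUE)
  expect_equal(mogp_lml(X, matrix(0, 4, 3), kp, cg3),
               as.numeric(-0.5 * determinant(K)$modulus - 0.5 * 12 * log(2 * pi)),
               tolerance = 1e-8)
})

test_that("Kronecker and dense LML routes agree with the dense-solve oracle", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 5; m <- 2
    X <- fix_design(n, seed = rep)
    Y <- matrix(rnorm(n * m), n, m)
    kp <- kernel_params(runif(1, 0.1, 1), runif(1, 0.5, 2), runif(1, 0.5, 2),
                        runif(1, 0.1, 0.5))
    cg <- fix_coreg(m, 2, seed = rep + 10)
    expect_equal(mogp_lml(X, Y, kp, cg), oracle_lml(X, Y, kp, cg),
                 tolerance = 1e-8)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(5)
  n <- 6; m <- 3; R <- 2
  X <- fix_design(n, seed = 5)
  Y <- matrix(rnorm(n * m), n, m)
  pre <- neonorm:::mogp_precompute(X)
  th <- neonorm:::theta_pack(fix_kernel(), fix_coreg(m, R, seed = 6))
  g <- neonorm:::kron_lml_grad(th, pre, Y, m, R, 1)$grad
  gn <- vapply(seq_along(th), function(i) {
    h <- 1e-6; tp <- th; tm <- th
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (neonorm:::kron_lml_grad(tp, pre, Y, m, R, 1, FALSE)$lml -
        neonorm:::kron_lml_grad(tm, pre, Y, m, R, 1, FALSE)$lml) / (2 * h)
  }, numeric(1))
  expect_equal(g, gn, tolerance = 1e-4)
})

test_that("predictions match the textbook closed-form oracle", {
  set.seed(31)
  n <- 8; m <- 3
  X <- fix_design(n, seed = 31)
  Y <- matrix(rnorm(n * m), n, m)
  kp <- fix_kernel(); cg <- fix_coreg(m, 2, seed = 32)
  fit <- structure(list(kernel = kp, coreg = cg, noise = "coupled",
                        X = X, Y = Y, Xs = X, Ys = Y,
                        x_center = rep(0, 3), x_scale = rep(1, 3),
                        y_center = rep(0, m), y_scale = rep(1, m),
                        n_outputs = m), class = "mogp_fit")
  Xn <- fix_design(3, seed = 33)
  for (i in seq_len(m)) {
    for (inc in c(FALSE, TRUE)) {
      p <- predict(fit, Xn, output_index = i, include_noise = inc)
      o <- oracle_predict(X, Y, kp, cg, Xn, i, include_noise = inc)
      expect_equal(drop(p$mean), o$mean, tolerance = 1e-8)
      expect_equal(drop(p$sd)^2, o$var, tolerance = 1e-8)
    }
  }
  # noise-inclusive minus latent variance is the constant noise share
  pn <- predict(fit, Xn, output_index = 1, include_noise = TRUE)
  pl <- predict(fit, Xn, output_index = 1, include_noise = FALSE)
  dv <- pn$sd^2 - pl$sd^2
  expect_equal(drop(dv), rep(coreg_matrix(cg)[1, 1] * kp$white_variance, 3),
               tolerance = 1e-10)
})

test_that("ICM with B = I reproduces independent single-output GPs", {
  set.seed(41)
  n <- 10; m <- 5
  X <- fix_design(n, seed = 41)
  Y <- matrix(rnorm(n * m), n, m)
  kp <- fix_kernel()
  cg_i <- coreg_params(matrix(0, m, 1), rep(1, m))
  joint <- structure(list(kernel = kp, coreg = cg_i, noise = "coupled",
                          X = X, Y = Y, Xs = X, Ys = Y,
                          x_center = rep(0, 3), x_scale = rep(1, 3),
                          y_center = rep(0, m), y_scale = rep(1, m),
                          n_outputs = m), class = "mogp_fit")
  Xn <- fix_design(4, seed = 42)
  cg_1 <- coreg_params(matrix(0, 1, 1), 1)
  for (i in seq_len(m)) {
    single <- structure(list(kernel = kp, coreg = cg_1, noise = "coupled",
                             X = X, Y = Y[, i, drop = FALSE], Xs = X,
                             Ys = Y[, i, drop = FALSE],
                             x_center = rep(0, 3), x_scale = rep(1, 3),
                             y_center = 0, y_scale = 1, n_outputs = 1),
                        class = "mogp_fit")
    pj <- predict(joint, Xn, output_index = i)
    ps <- predict(single, Xn, output_index = 1)
    expect_equal(pj$mean, ps$mean, tolerance = 1e-6)
    expect_equal(pj$sd, ps$sd, tolerance = 1e-6)
  }
  # LML separates additively over outputs
  lml_joint <- mogp_lml(X, Y, kp, cg_i)
  lml_sum <- sum(vapply(seq_len(m), function(i)
    mogp_lml(X, Y[, i, drop = FALSE], kp, cg_1), numeric(1)))
  expect_equal(lml_joint, lml_sum, tolerance = 1e-6)
})

test_that("coupled and independent noise models agree when B is diagonal", {
  set.seed(43)
  n <- 5; m <- 2
  X <- fix_design(n, seed = 43)
  Y <- matrix(rnorm(n * m), n, m)
  kp <- fix_kernel()
  cg <- coreg_params(matrix(0, m, 1), rep(1, m))  # B = I
  expect_equal(mogp_lml(X, Y, kp, cg, noise = "coupled"),
               mogp_lml(X, Y, kp, cg, noise = "independent"),
               tolerance = 1e-8)
})

test_that("optimizer recovers a flat function as white noise", {
  set.seed(51)
  n <- 100
  X <- fix_design(n, seed = 51)
  Y <- matrix(rnorm(n, 0, 1), n, 1)      # pure white noise, no signal
  fit <- mogp_fit(X, Y, rank = 1, n_restarts = 2, seed = 1, standardize = FALSE)
  expect_lt(fit$kernel$rbf_variance * coreg_matrix(fit$coreg)[1, 1],
            0.1 * fit$kernel$white_variance * coreg_matrix(fit$coreg)[1, 1] + 1e-6)
})

test_that("optimizer behaves as a fixed point and dominates the truth", {
  set.seed(53)
  n <- 40; m <- 2
  X <- fix_design(n, seed = 53)
  kp_true <- kernel_params(0.05, 1, 1.2, 0.3)
  cg_true <- fix_coreg(m, 1, seed = 54)
  K <- icm_covariance(kp_true, cg_true, scale(X[, 1:2]) |> cbind(X[, 3]),
                      include_white = TRUE)
  y <- drop(chol(K + diag(1e-10, nrow(K))) %*% rnorm(n * m))
  Y <- matrix(y, n, m)
  fit <- mogp_fit(X, Y, rank = 1, n_restarts = 2, seed = 7, standardize = FALSE)
  # LML at the returned params is at least that of the generating params
  lml_true <- mogp_lml(X, Y, kp_true, cg_true)
  expect_gte(fit$lml, lml_true - 1e-6)
  # re-optimizing from the optimum barely moves the LML
  fit2 <- mogp_fit(X, Y, init = list(kernel = fit$kernel, coreg = fit$coreg),
                   rank = 1, n_restarts = 1, seed = 7, standardize = FALSE)
  expect_lt(abs(fit2$lml - fit$lml), 1e-4)
  expect_gte(fit2$lml, fit$lml - 1e-6)
})

test_that("fits are deterministic given a seed and interpolate as noise -> 0", {
  set.seed(61)
  n <- 25
  X <- fix_design(n, seed = 61)
  Y <- matrix(sin(X[, 1] / 3) + 0.01 * rnorm(n), n, 1)
  f1 <- mogp_fit(X, Y, rank = 1, n_restarts = 2, seed = 5)
  f2 <- mogp_fit(X, Y, rank = 1, n_restarts = 2, seed = 5)
  expect_identical(f1$lml, f2$lml)
  expect_identical(f1$kernel, f2$kernel)
  # interpolation limit: prediction at a training point approaches the datum
  p <- predict(f1, X[3, , drop = FALSE], output_index = 1)
  expect_lt(abs(p$mean[1, 1] - Y[3, 1]), 0.1)
})

test_that("standardize-fit-predict is affine-equivariant", {
  set.seed(71)
  n <- 30
  X <- fix_design(n, seed = 71)
  Y <- matrix(2 + 0.1 * X[, 1] + rnorm(n, 0, 0.2), n, 1)
  fit_raw <- mogp_fit(X, Y, rank = 1, n_restarts = 1, seed = 3)
  a <- 10; b <- 4
  fit_tr <- mogp_fit(X, a * Y + b, rank = 1, n_restarts = 1, seed = 3)
  Xn <- fix_design(5, seed = 72)
  p1 <- predict(fit_raw, Xn, output_index = 1)
  p2 <- predict(fit_tr, Xn, output_index = 1)
  expect_equal(a * p1$mean + b, p2$mean, tolerance = 1e-6)
  expect_equal(a * p1$sd, p2$sd, tolerance = 1e-6)
})

test_that("predictive variance does not increase when a training point is added at the query", {
  set.seed(81)
  n <- 8
  X <- fix_design(n, seed = 81)
  Y <- matrix(rnorm(n), n, 1)
  kp <- fix_kernel(); cg <- coreg_params(matrix(0, 1, 1), 1)
  xq <- matrix(c(1.2, 0.5, 1), 1, 3)
  mk_fit <- function(X, Y) structure(
    list(kernel = kp, coreg = cg, noise = "coupled", X = X, Y = Y, Xs = X,
         Ys = Y, x_center = rep(0, 3), x_scale = rep(1, 3), y_center = 0,
         y_scale = 1, n_outputs = 1), class = "mogp_fit")
  v_before <- predict(mk_fit(X, Y), xq, output_index = 1)$sd^2
  v_after <- predict(mk_fit(rbind(X, xq), rbind(Y, 0)), xq, output_index = 1)$sd^2
  expect_lte(v_after[1, 1], v_before[1, 1] + 1e-10)
})

test_that("degenerate inputs raise argument errors", {
  expect_error(mogp_fit(fix_design(2), matrix(1:2, 2, 1)), "at least 3")
  X <- fix_design(5)
  expect_error(mogp_fit(X, matrix(1, 5, 1)), "degenerate")
})
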