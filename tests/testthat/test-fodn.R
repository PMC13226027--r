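test_that("GL coefficients: closed forms and the log-gamma oracle", {
  expect_equal(gl_coefficients(0, 5), c(1, 0, 0, 0, 0, 0))
  expect_equal(gl_coefficients(1, 5), c(1, -1, 0, 0, 0, 0))
  expect_equal(gl_coefficients(0.5, 2), c(1, -0.5, -0.125))
  for (al in c(0.2, 0.5, 0.8)) {
    expect_equal(gl_coefficients(al, 50), gl_coef_gamma(al, 50),
                 tolerance = 1e-10)
  }
})

test_that("GL derivative reduces to identity and first difference", {
  set.seed(4)
  x <- rnorm(300)
  expect_equal(gl_derivative(x, 0, 10), x[11:300], tolerance = 1e-12)
  expect_equal(gl_derivative(x, 1, 10), diff(x)[10:299], tolerance = 1e-12)
  # direct Gamma-formula convolution oracle at fractional order
  al <- 0.3; J <- 40L
  cj <- gl_coef_gamma(al, J)
  z_oracle <- vapply((J + 1):300, function(k) sum(cj * x[k - 0:J]), numeric(1))
  expect_equal(gl_derivative(x, al, J), z_oracle, tolerance = 1e-9)
  expect_error(gl_derivative(x, 0.5, 300), "smaller than length")
})

test_that("wavelet alpha regression is unbiased on white noise and scale-free", {
  est <- vapply(1:20, function(s) {
    set.seed(s); estimate_alpha(rnorm(8192), levels = 6)$alpha
  }, numeric(1))
  expect_gte(mean(est), -0.1)
  expect_lte(mean(est), 0.1)
  set.seed(30)
  x <- rnorm(600)
  expect_equal(estimate_alpha(5 * x)$alpha, estimate_alpha(x)$alpha,
               tolerance = 1e-12)
  expect_error(estimate_alpha(rnorm(20), levels = 4), "at least 32")
})

test_that("noiseless simulation round-trips through the network fit", {
  # a noiseless free response decays, so the planted system must be close
  # to marginal for its trajectory to stay numerically alive: skew
  # (rotation) coupling, near-unit fractional orders, a rich initial
  # state spanning the GL history, and a tiny uniform leak
  set.seed(3)
  n <- 8
  S <- matrix(rnorm(n * n, sd = 0.4), n, n) * (matrix(runif(n * n), n, n) < 0.4)
  S <- S - t(S)
  S <- S * (0.25 / max(Mod(eigen(S, only.values = TRUE)$values)))
  tr <- list(A = S - diag(1e-3, n), alpha = runif(n, 0.85, 0.95), J = 50L)
  expect_lt(adsuppress:::.gl_companion_radius(tr$A, tr$alpha, tr$J), 1)
  X <- simulate_fodn(tr, 300, noise_sd = 0, seed = 2, init_len = tr$J)
  fit <- suppressWarnings(
    fit_fodn(X, lambda_ridge = 1e-8 * mean(X^2) * nrow(X), alpha = tr$alpha,
             J = tr$J))
  relF <- sqrt(sum((fit$A - tr$A)^2)) / sqrt(sum(tr$A^2))
  expect_lt(relF, 1e-3)
})

test_that("ridge solution approaches least squares as lambda -> 0", {
  set.seed(6)
  n <- 5; m <- 400
  A0 <- matrix(rnorm(n * n, sd = 0.3), n, n)
  Xm <- matrix(rnorm(n * m), n, m)
  Zm <- A0 %*% Xm + matrix(rnorm(n * m, sd = 0.01), n, m)
  ls <- t(solve(tcrossprod(Xm), tcrossprod(Xm, Zm)))
  ridge <- t(solve(tcrossprod(Xm) + diag(1e-10, n), tcrossprod(Xm, Zm)))
  expect_lt(sqrt(sum((ridge - ls)^2)), 1e-6)
})

test_that("LASSO limit kills every input; zero regressors give a zero matrix", {
  tr <- random_fodn_truth(6, seed = 3)
  X <- simulate_fodn(tr, 800, noise_sd = 0.1, seed = 4)
  fit <- fit_fodn(X, lambda_lasso = 1e6, alpha = tr$alpha, J = tr$J)
  expect_true(all(fit$U == 0))
  fit0 <- fit_fodn(matrix(0, 300, 4), lambda_ridge = 1, lambda_lasso = 0.1,
                   alpha = rep(0, 4), J = 50)
  expect_true(all(fit0$A == 0))
  expect_error(fit_fodn(matrix(0, 300, 4), lambda_ridge = 0,
                        alpha = rep(0, 4), J = 50), "lambda_ridge > 0")
})

test_that("alternation never increases its objective or residual", {
  for (s in 1:3) {
    tr <- random_fodn_truth(6, seed = 10 + s)
    X <- simulate_fodn(tr, 900, noise_sd = 0.2, seed = 20 + s)
    fit <- fit_fodn(X, n_alt_iters = 5, J = tr$J)
    expect_true(all(diff(fit$objective) <= 1e-8 * (1 + abs(fit$objective[1]))))
    expect_true(all(diff(fit$resid_fro) <= 1e-8 * (1 + fit$resid_fro[1])))
  }
})

test_that("dominant eigenmode follows the modulus-and-sign conventions", {
  em <- dominant_eigvec(diag(c(0.9, 0.5, 0.1)))
  expect_equal(em$lambda_mod, 0.9)
  expect_equal(em$weights, c(1, 0, 0))
  expect_equal(em$participation, 1 / 3)

  em2 <- dominant_eigvec(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(em2$lambda_mod, 1)
  expect_equal(em2$weights, rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(em2$participation, 1)

  # rotation by 90 degrees: complex pair, modulus convention
  em3 <- dominant_eigvec(matrix(c(0, 1, -1, 0), 2, 2))
  expect_equal(em3$lambda_mod, 1)
  expect_equal(em3$weights, rep(1 / sqrt(2), 2), tolerance = 1e-12)
  # brute-force eigen oracle confirms the convention output
  ev <- eigen(matrix(c(0, 1, -1, 0), 2, 2))
  v <- ev$vectors[, which.max(Mod(ev$values))]
  expect_equal(em3$weights, Mod(v / sqrt(sum(Mod(v)^2))), tolerance = 1e-12)
  expect_error(dominant_eigvec(matrix(c(1, NA, 0, 1), 2, 2)), "non-finite")
})

test_that("windowed network tracks have the channels-by-windows layout", {
  co <- small_cohort()
  tr <- co[[2]]
  rec <- zscore_channels(tr$recording)
  grid <- make_windows(rec, tr$timeline, "W2", "nonoverlap")
  fk <- windowed_fodn(rec, grid)
  expect_equal(dim(fk$alpha_track), c(12L, nrow(grid)))
  expect_equal(dim(fk$eig_track), c(12L, nrow(grid)))
  expect_true(all(is.finite(fk$spectral_radius)))
  expect_true(all(abs(colSums(fk$eig_track^2) - 1) < 1e-8))
})

test_that("a stationary planted network yields a stable dominant mode", {
  # plant a well-separated dominant mode so there is a stable mode to track
  tr <- random_fodn_truth(10, diag_spread = 0, seed = 5)
  tr$A[3, 3] <- tr$A[3, 3] - 0.3
  X <- simulate_fodn(tr, 12000, noise_sd = 0.5, seed = 6)
  rec <- recording(X, fs_hz = 1000)
  tl <- timeline(c("AD_Start", "Qes_Start", "AD_End"), c(0, 0.5, 12),
                 rec = rec)
  grid <- make_windows(rec, tl, "W2", "nonoverlap", window_s = 1)
  fk <- windowed_fodn(rec, grid, lambda_ridge = 20, alpha = tr$alpha,
                      J = tr$J)
  expect_gte(fk$cos_stability, 0.9)
})
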