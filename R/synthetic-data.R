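#' Exact fractional Gaussian noise by circulant embedding
#'
#' Synthesises a stationary Gaussian series whose autocovariance is exactly
#' that of fractional Gaussian noise (fGn) with Hurst exponent `hurst`:
#' `gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) / 2`. The covariance is
#' embedded in a circulant matrix of order `2n` whose eigenvalues are obtained
#' by FFT; a complex Gaussian vector is coloured by their square roots, so the
#' synthesis is exact whenever the embedding is nonnegative definite (it is
#' for fGn at all `H` in (0,1); small negative eigenvalues from floating-point
#' rounding are clipped, larger ones raise an error).
#'
#' @param hurst Hurst exponent, strictly inside (0, 1). `H = 0.5` is white
#'   noise; `H > 0.5` long-range dependent (persistent).
#' @param n Series length (>= 64).
#' @param seed Optional RNG seed; identical seeds give identical series.
#' @return Numeric vector of length `n` with unit marginal variance.
#' @export
gen_fgn <- function(hurst, n, seed = NULL) {
  if (!is.numeric(hurst) || length(hurst) != 1L || !is.finite(hurst) ||
      hurst <= 0 || hurst >= 1) {
    stop("`hurst` must lie strictly inside (0, 1)", call. = FALSE)
  }
  n <- .assert_count(n, "n", min = 64L)
  h2 <- 2 * hurst
  k <- 0:n
  gam <- 0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
  row <- c(gam, rev(gam[2:n]))            # circulant first row, length 2n
  m <- length(row)
  ev <- Re(stats::fft(row))
  tol <- 1e-10 * max(ev)
  if (any(ev < -tol)) {
    stop("circulant embedding is not nonnegative definite (min eigenvalue ",
         format(min(ev)), "); cannot synthesise exactly", call. = FALSE)
  }
  ev <- pmax(ev, 0)
  with_seed(seed, {
    w <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    x <- stats::fft(sqrt(ev / m) * w)
    Re(x)[seq_len(n)]
  })
}

#' Fractionally integrated white noise (ARFIMA(0, d, 0))
#'
#' Applies the fractional integration operator `(1 - B)^{-d}` to Gaussian
#' white noise through its MA(infinity) expansion
#' `psi_j = Gamma(j + d) / (Gamma(d) Gamma(j + 1))`, computed by the stable
#' recursion `psi_j = psi_{j-1} (j - 1 + d) / j` and truncated at `n_psi`
#' lags (default: the series length). The filter is applied by FFT
#' convolution after an `n_psi`-sample burn-in, so the returned segment is
#' (truncation aside) stationary. The spectral density behaves as
#' `f^{-2d}` at low frequency, i.e. the wavelet log-scale regression slope
#' is `2d` and the fractional order `alpha = d`.
#'
#' @param d Fractional integration order, `|d| < 0.5`.
#' @param n Output length.
#' @param seed Optional RNG seed.
#' @param n_psi Truncation depth of the MA expansion (default `n`).
#' @return Numeric vector of length `n`; the aligned driving noise is
#'   attached as attribute `"innovations"` (at `d = 0` the output equals it).
#' @export
gen_arfima <- function(d, n, seed = NULL, n_psi = n) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || abs(d) >= 0.5) {
    stop("`d` must satisfy |d| < 0.5", call. = FALSE)
  }
  n <- .assert_count(n, "n", min = 2L)
  n_psi <- .assert_count(n_psi, "n_psi", min = 1L)
  with_seed(seed, {
    eps <- stats::rnorm(n + n_psi)
    x <- .arfima_filter(matrix(eps, ncol = 1L), d, n, n_psi)[, 1L]
    attr(x, "innovations") <- eps[(n_psi + 1L):(n_psi + n)]
    x
  })
}

# Batched fractional integration: eps is (n + L) x m (burn-in of L rows),
# d is scalar or length-m; returns the last n rows of the causal filter
# x_t = sum_{j=0}^{L} psi_j eps_{t-j}, one psi sequence per column.
.arfima_filter <- function(eps, d, n, L) {
  m <- ncol(eps)
  d <- rep_len(d, m)
  psi <- matrix(0, nrow = L + 1L, ncol = m)
  psi[1L, ] <- 1
  if (L >= 1L) {
    for (j in seq_len(L)) psi[j + 1L, ] <- psi[j, ] * (j - 1 + d) / j
  }
  P <- stats::nextn(nrow(eps) + L + 1L, 2)
  ep <- rbind(eps, matrix(0, P - nrow(eps), m))
  kp <- rbind(psi, matrix(0, P - nrow(psi), m))
  conv <- Re(stats::mvfft(stats::mvfft(ep) * stats::mvfft(kp), inverse = TRUE)) / P
  conv[(L + 1L):(L + n), , drop = FALSE]
}

#' Deterministic binomial multiplicative cascade
#'
#' Builds the canonical binomial multifractal series of length `2^n_levels`:
#' starting from a unit mass, every dyadic interval repeatedly splits its
#' mass into fractions `a` (left) and `1 - a` (right). Its generalized Hurst
#' exponent is known in closed form,
#' `h(q) = 1/q - log2(a^q + (1-a)^q)/q`, making it the standard oracle for
#' multifractal DFA implementations.
#'
#' @param a Mass multiplier, strictly inside (0.5, 1). As `a -> 0.5` the
#'   series degenerates to a constant and `h(q) -> 1` for all q.
#' @param n_levels Number of dyadic refinement levels; output length
#'   `2^n_levels`.
#' @return Numeric vector of length `2^n_levels`.
#' @seealso [cascade_hq()] for the closed-form exponent.
#' @export
gen_binomial_cascade <- function(a, n_levels) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0.5 || a >= 1) {
    stop("`a` must lie strictly inside (0.5, 1)", call. = FALSE)
  }
  n_levels <- .assert_count(n_levels, "n_levels", min = 1L)
  x <- 1
  for (lev in seq_len(n_levels)) x <- c(a * x, (1 - a) * x)
  x
}

#' Closed-form generalized Hurst exponent of the binomial cascade
#'
#' @param a Cascade multiplier in (0.5, 1).
#' @param q Moment orders (vector); `q = 0` is handled by its limit
#'   `-log2(a (1 - a)) / 2`.
#' @return `h(q)`, same length as `q`.
#' @export
cascade_hq <- function(a, q) {
  h <- ifelse(q == 0,
              -log2(a * (1 - a)) / 2,
              1 / q - log2(a^q + (1 - a)^q) / q)
  as.numeric(h)
}

#' Random ground-truth fractional-order network
#'
#' Draws a sparse directed coupling matrix `A` and per-channel fractional
#' orders for use with [simulate_fodn()] and parameter-recovery tests.
#' Because the truncated-GL integrator is only marginally stable, coupling
#' eigenvalues with positive real part diverge: the off-diagonal couplings
#' are therefore rescaled to spectral radius `rho` and the diagonal is
#' shifted so every eigenvalue of `A` has real part at most `-margin`.
#' With `check = "companion"` (the default) the exact linearisation of the
#' truncated-GL dynamics -- the `n*J` block companion matrix built from `A`
#' and the drawn orders -- is then required to have spectral radius < 1,
#' shrinking the couplings until it does, so every returned truth simulates
#' stably.
#'
#' @param n_channels Network size.
#' @param density Expected fraction of nonzero off-diagonal couplings
#'   (default `5 / n_channels`, i.e. about five inputs per channel).
#' @param rho Spectral radius of the off-diagonal coupling part before the
#'   stabilising shift (the spectral radius of the returned `A` stays
#'   below 1).
#' @param alpha_range Range the per-channel fractional orders are drawn from
#'   (uniform); entries must lie in [0, 1.5].
#' @param margin All eigenvalues of `A` are moved to real part <= -margin.
#' @param diag_spread Width of the additional per-channel self-damping,
#'   drawn uniformly from `[0, diag_spread]` and subtracted from each
#'   diagonal entry: channels leak at heterogeneous rates, as real
#'   electrode populations do.
#' @param J Grunwald-Letnikov truncation depth carried with the truth so
#'   that simulation and fitting share the same discrete operator.
#' @param check `"companion"` verifies stability of the full truncated-GL
#'   linearisation (an `n*J` eigenproblem); `"spectral"` only enforces
#'   `rho(A) < 1` (sufficient when the orders are not simulated, e.g. the
#'   cohort generator's one-step mixing).
#' @param seed Optional RNG seed.
#' @return List with `A`, `alpha`, `J`, `rho`.
#' @export
random_fodn_truth <- function(n_channels, density = 5 / n_channels, rho = 0.5,
                              alpha_range = c(0.2, 0.8), margin = 0.05,
                              diag_spread = 0.4, J = 50L,
                              check = c("companion", "spectral"),
                              seed = NULL) {
  n_channels <- .assert_count(n_channels, "n_channels", min = 2L)
  check <- match.arg(check)
  if (rho <= 0 || rho >= 1) stop("`rho` must lie in (0, 1)", call. = FALSE)
  if (min(alpha_range) < 0 || max(alpha_range) > 1.5) {
    stop("`alpha_range` must lie within [0, 1.5]", call. = FALSE)
  }
  J <- .assert_count(J, "J", min = 1L)
  with_seed(seed, {
    Aoff <- matrix(stats::rnorm(n_channels^2), n_channels, n_channels) *
      (matrix(stats::runif(n_channels^2), n_channels, n_channels) < density)
    diag(Aoff) <- 0
    sr <- max(Mod(eigen(Aoff, only.values = TRUE)$values))
    if (sr > 0) Aoff <- Aoff * (rho / sr)
    alpha <- stats::runif(n_channels, alpha_range[1L], alpha_range[2L])
    leak <- stats::runif(n_channels, 0, diag_spread)
    shrink <- 1
    for (attempt in 1:12) {
      A <- shrink * Aoff
      maxRe <- max(Re(eigen(A, only.values = TRUE)$values))
      A <- A - diag(maxRe + margin + leak)
      if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1) {
        shrink <- shrink * 0.8
        next
      }
      if (check == "spectral" || .gl_companion_radius(A, alpha, J) < 1 - 1e-8) break
      shrink <- shrink * 0.8
      if (attempt == 12L) stop("could not stabilise the drawn network", call. = FALSE)
    }
    list(A = A, alpha = alpha, J = J, rho = rho)
  })
}

# Spectral radius of the block companion linearisation of the truncated-GL
# network x[k] = (A - C_1) x[k-1] - C_2 x[k-2] - ... - C_J x[k-J], with
# C_j = diag(c_j^{alpha_i}).
.gl_companion_radius <- function(A, alpha, J) {
  n <- nrow(A)
  C <- vapply(alpha, gl_coefficients, numeric(J + 1L), J = J)  # (J+1) x n
  M <- matrix(0, n * J, n * J)
  M[seq_len(n), seq_len(n)] <- A - diag(C[2L, ], n)
  if (J >= 2L) {
    for (j in 2:J) {
      M[seq_len(n), (j - 1L) * n + seq_len(n)] <- -diag(C[j + 1L, ], n)
    }
    M[cbind(n + seq_len(n * (J - 1L)), seq_len(n * (J - 1L)))] <- 1
  }
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' Simulate a fractional-order dynamical network forward
#'
#' Iterates the discrete model `z[k] = A x[k-1] + u[k] + eps[k]`, where
#' `z[k]` is the truncated Grunwald-Letnikov fractional derivative of the
#' state (`z_i[k] = sum_{j=0..J} c_j^{alpha_i} x_i[k-j]`), by inverting the
#' operator one step at a time: since `c_0 = 1`,
#' `x[k] = A x[k-1] - sum_{j=1..J} c_j x[k-j] + u[k] + eps[k]`.
#' The generator and [fit_fodn()] share the same truncation depth `J`, so a
#' noiseless simulation lies exactly on the fitted model class.
#'
#' @param truth List with `A` (n x n, spectral radius < 1), `alpha`
#'   (length n, in [0, 1.5]) and optionally `J` (default 50) -- e.g. from
#'   [random_fodn_truth()].
#' @param t_samples Number of time samples to generate.
#' @param noise_sd Innovation standard deviation (0 gives a noiseless
#'   trajectory started from a random initial state).
#' @param seed Optional RNG seed.
#' @param u Optional n x t_samples input matrix (default zero).
#' @param init_len Number of leading samples drawn i.i.d. N(0,1) as the
#'   pre-stimulus state before the dynamics take over (default 1). A
#'   noiseless run needs `init_len` near `J` for its trajectory to span
#'   all state directions (a single initial vector excites only a
#'   low-dimensional Krylov subspace).
#' @return `t_samples x n` matrix of signals, with the realised inputs and
#'   innovations attached as attributes `"u"` and `"eps"`.
#' @export
simulate_fodn <- function(truth, t_samples, noise_sd = 1, seed = NULL,
                          u = NULL, init_len = 1L) {
  A <- as.matrix(truth$A)
  alpha <- truth$alpha
  J <- if (!is.null(truth$J)) as.integer(truth$J) else 50L
  n <- nrow(A)
  if (ncol(A) != n) stop("`A` must be square", call. = FALSE)
  if (length(alpha) != n) {
    stop("`alpha` must have one entry per channel", call. = FALSE)
  }
  ev <- eigen(A, only.values = TRUE)$values
  sr <- max(Mod(ev))
  if (sr >= 1) {
    stop(sprintf("unstable coupling matrix: eigenvalue %s has modulus %.4f >= 1",
                 format(ev[which.max(Mod(ev))], digits = 4), sr), call. = FALSE)
  }
  t_samples <- .assert_count(t_samples, "t_samples", min = 2L)
  if (is.null(u)) u <- matrix(0, n, t_samples)
  if (!all(dim(u) == c(n, t_samples))) {
    stop("`u` must be n_channels x t_samples", call. = FALSE)
  }
  # per-channel GL coefficients, rows j = 0..J
  C <- vapply(alpha, gl_coefficients, numeric(J + 1L), J = J)
  Ct <- t(C)                               # n x (J+1), column j+1 holds c_j
  with_seed(seed, {
    eps <- matrix(stats::rnorm(n * t_samples, sd = noise_sd), n, t_samples)
    x <- matrix(0, n, t_samples)
    init_len <- max(1L, min(as.integer(init_len), t_samples - 1L))
    x[, seq_len(init_len)] <- stats::rnorm(n * init_len)
    for (k in (init_len + 1L):t_samples) {
      jmax <- min(k - 1L, J)
      xpast <- x[, k - seq_len(jmax), drop = FALSE]        # n x jmax
      glsum <- rowSums(Ct[, 1L + seq_len(jmax), drop = FALSE] * xpast)
      x[, k] <- A %*% x[, k - 1L] - glsum + u[, k] + eps[, k]
      if (any(!is.finite(x[, k])) || max(abs(x[, k])) > 1e12) {
        stop("simulation diverged at sample ", k,
             "; reduce spectral radius or alpha", call. = FALSE)
      }
    }
    out <- t(x)
    attr(out, "u") <- u
    attr(out, "eps") <- eps
    out
  })
}
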