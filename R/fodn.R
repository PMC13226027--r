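#' Grunwald-Letnikov fractional-difference coefficients
#'
#' Coefficients of the truncated Grunwald-Letnikov fractional derivative of
#' order `alpha`, `c_j = Gamma(j - alpha) / (Gamma(-alpha) Gamma(j + 1))`,
#' computed by the numerically stable recursion
#' `c_0 = 1, c_j = c_{j-1} (j - 1 - alpha) / j` (the Gamma-ratio form
#' overflows/0-divides at nonnegative integer `alpha`; the recursion does
#' not). `alpha = 0` gives the identity, `alpha = 1` the first difference.
#'
#' @param alpha Fractional order (any real).
#' @param J Truncation depth; returns `c_0 ... c_J`.
#' @return Numeric vector of length `J + 1`.
#' @export
gl_coefficients <- function(alpha, J) {
  J <- .assert_count(J, "J", min = 0L)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha)) {
    stop("`alpha` must be a single finite number", call. = FALSE)
  }
  cj <- numeric(J + 1L)
  cj[1L] <- 1
  if (J >= 1L) {
    for (j in seq_len(J)) cj[j + 1L] <- cj[j] * (j - 1 - alpha) / j
  }
  cj
}

#' Grunwald-Letnikov fractional derivative of a signal
#'
#' `z[k] = sum_{j=0}^{J} c_j^{alpha} x[k-j]`, returned only on the fully
#' initialised range `k = J+1 ... N` (the first `J` samples lack complete
#' history and are dropped from downstream regressions).
#'
#' @param x Numeric vector.
#' @param alpha Fractional order.
#' @param J Truncation depth, `J < length(x)`.
#' @return Numeric vector of length `length(x) - J`.
#' @export
gl_derivative <- function(x, alpha, J) {
  J <- .assert_count(J, "J", min = 0L)
  if (J >= length(x)) stop("`J` must be smaller than length(x)", call. = FALSE)
  drop(.gl_derivative_matrix(matrix(x, ncol = 1L), alpha, J))
}

# Batched GL derivative with per-channel orders: X is N x m, alpha scalar or
# length m; returns (N - J) x m via FFT convolution.
.gl_derivative_matrix <- function(X, alpha, J) {
  N <- nrow(X)
  m <- ncol(X)
  alpha <- rep_len(alpha, m)
  C <- matrix(0, J + 1L, m)                # c_j per column, vectorised recursion
  C[1L, ] <- 1
  for (j in seq_len(J)) C[j + 1L, ] <- C[j, ] * (j - 1 - alpha) / j
  P <- stats::nextn(N + J + 1L, 2)
  xp <- rbind(X, matrix(0, P - N, m))
  kp <- rbind(C, matrix(0, P - (J + 1L), m))
  conv <- Re(stats::mvfft(stats::mvfft(xp) * stats::mvfft(kp), inverse = TRUE)) / P
  conv[(J + 1L):N, , drop = FALSE]
}

#' Fractional order from a Haar wavelet log-scale regression
#'
#' Estimates a channel's fractional order from the slope of its Haar wavelet
#' energy spectrum: detail coefficients are computed at levels
#' `j = 1 ... levels`, `mu_j` is the mean squared detail coefficient at level
#' j, `p` is the least-squares slope of `log2 mu_j` against `j`, and
#' `alpha = p / 2`. For a process with spectral density `f^{-gamma}` the
#' slope is `gamma`, so fractionally integrated noise of order `d` yields
#' `alpha = d`; white noise yields `alpha = 0`.
#'
#' At the fine dyadic scales this regression can use, the discrete
#' fractional operator's spectrum `|2 sin(w/2)|^(-2 alpha)` deviates from
#' the pure power law `|w|^(-2 alpha)`, which biases the raw slope towards
#' zero. With `correct = TRUE` (the default) the raw slope is mapped
#' through the inverse of the exact relation between `alpha` and the
#' expected regression slope (computed by numerical integration of the
#' Haar filter response against the discrete spectrum, once per level
#' range), removing that discretisation bias.
#'
#' @param x Numeric signal of length at least `2^(levels + 1)`.
#' @param levels Number of dyadic levels in the regression (default 4, the
#'   choice used for 500-sample analysis windows).
#' @param correct Apply the finite-scale slope correction (default TRUE).
#' @return List with `alpha`, `slope` (`p`, uncorrected), and the level
#'   energies `mu`.
#' @export
estimate_alpha <- function(x, levels = 4L, correct = TRUE) {
  levels <- .assert_count(levels, "levels", min = 2L)
  if (length(x) < 2^(levels + 1L)) {
    stop(sprintf("signal too short: need at least %d samples for %d levels",
                 2^(levels + 1L), levels), call. = FALSE)
  }
  res <- .alpha_matrix(matrix(x, ncol = 1L), levels, correct = correct)
  list(alpha = res$alpha[1L], slope = res$slope[1L], mu = res$mu[, 1L])
}

# Expected Haar level energies E_j under the discrete fractional spectrum
# S(w) = |2 sin(w/2)|^(-2 alpha): numerical integral of S against the
# orthonormal Haar filter response at level j.
.haar_level_energy <- function(alpha, levels) {
  vapply(seq_len(levels), function(j) {
    f <- function(w) {
      S <- (2 * sin(w / 2))^(-2 * alpha)
      Hj <- 2 * sin(2^(j - 1) * w / 2)^2
      if (j >= 2L) for (l in 0:(j - 2L)) Hj <- Hj * 2 * cos(2^l * w / 2)^2
      S * Hj
    }
    stats::integrate(f, 1e-9, pi, subdivisions = 2000L,
                     rel.tol = 1e-9)$value / pi
  }, numeric(1))
}

# Model-aware Haar slope map: expected level energies when channel i obeys
# C_J(w; alpha) x_i = a_ii x_i[k-1] + white noise, i.e. spectrum
# |C_J(w) - a e^{-iw}|^{-2}. Grid quadrature (the self-coupling bounds the
# integrand away from the w -> 0 singularity). Returns, for one `a`, the
# slope of log2 E_j over j = 1..levels at each alpha of `agrid`.
.haar_slope_damped <- function(agrid, a_self, levels, J = 50L, n_grid = 2048L) {
  w <- seq(1e-4, pi, length.out = n_grid)
  Ewj <- exp(-1i * outer(w, 0:J))                    # n_grid x (J+1)
  Hj <- vapply(seq_len(levels), function(j) {
    h <- 2 * sin(2^(j - 1) * w / 2)^2
    if (j >= 2L) for (l in 0:(j - 2L)) h <- h * 2 * cos(2^l * w / 2)^2
    h
  }, numeric(n_grid))                                # n_grid x levels
  dw <- w[2L] - w[1L]
  js <- seq_len(levels)
  vapply(agrid, function(al) {
    Cw <- Ewj %*% gl_coefficients(al, J)
    S <- 1 / Mod(Cw - a_self * exp(-1i * w))^2
    Ej <- colSums(as.numeric(S) * Hj) * dw / pi
    .ls_slope(js, matrix(log2(Ej), ncol = 1L))$slope
  }, numeric(1))
}

# Monotone map raw slope -> alpha for a given level count, cached.
.haar_slope_map_cache <- new.env(parent = emptyenv())
.haar_slope_map <- function(levels) {
  key <- as.character(levels)
  if (!is.null(.haar_slope_map_cache[[key]])) return(.haar_slope_map_cache[[key]])
  agrid <- seq(-0.45, 1.45, by = 0.05)
  js <- seq_len(levels)
  pgrid <- vapply(agrid, function(a) {
    .ls_slope(js, matrix(log2(.haar_level_energy(a, levels)), ncol = 1L))$slope
  }, numeric(1))
  map <- list(p = pgrid, alpha = agrid)
  .haar_slope_map_cache[[key]] <- map
  map
}

# Batched Haar wavelet alpha estimation over the columns of X.
.alpha_matrix <- function(X, levels = 4L, correct = TRUE) {
  m <- ncol(X)
  mu <- matrix(NA_real_, levels, m)
  a <- X
  for (j in seq_len(levels)) {
    n2 <- nrow(a) %/% 2L
    odd <- 2L * seq_len(n2) - 1L
    d <- (a[odd, , drop = FALSE] - a[odd + 1L, , drop = FALSE]) / sqrt(2)
    a <- (a[odd, , drop = FALSE] + a[odd + 1L, , drop = FALSE]) / sqrt(2)
    mu[j, ] <- colMeans(d^2)
  }
  ok <- colSums(!is.finite(mu) | mu <= 0) == 0
  slope <- rep(NA_real_, m)
  if (any(ok)) {
    fit <- .ls_slope(seq_len(levels), log2(mu[, ok, drop = FALSE]))
    slope[ok] <- fit$slope
  }
  if (correct) {
    map <- .haar_slope_map(levels)
    alpha <- stats::approx(map$p, map$alpha, xout = slope, rule = 2)$y
    alpha[!is.finite(slope)] <- NA_real_
  } else {
    alpha <- slope / 2
  }
  list(alpha = alpha, slope = slope, mu = mu)
}

#' Identify a fractional-order dynamical network on one data window
#'
#' Fits `z[k] = A x[k-1] + B u[k] + eps[k]` with `B = I`, where `z` is the
#' channelwise truncated Grunwald-Letnikov derivative of the data at orders
#' `alpha` (estimated per channel by [estimate_alpha()] when not supplied).
#' Estimation alternates (1) a ridge solve
#' `A = (Z - U) X^T (X X^T + lambda I)^{-1}` with (2) the per-time-step
#' LASSO input refinement, which with identity `B` is the soft-threshold
#' `u[k] = sign(r) max(|r| - lambda_lasso, 0)`, `r = z[k] - A x[k-1]`.
#' Each step decreases the joint objective
#' `||Z - A X - U||_F^2 + lambda_ridge ||A||_F^2 + 2 lambda_lasso sum|U|`,
#' which is recorded per iteration and asserted non-increasing.
#'
#' @param X Window data, samples x channels.
#' @param lambda_ridge Ridge weight; default `0.1 * mean(diag(X X^T))`
#'   (scales with the data so windows of different energy are penalised
#'   comparably).
#' @param lambda_lasso Soft-threshold level for the sparse inputs; default
#'   twice the MAD-based scale of the initial residuals, which on
#'   input-free data leaves >= 90% of the input entries at zero.
#' @param n_alt_iters Maximum alternation count (default 3).
#' @param alpha Optional known fractional orders (length = channels);
#'   when `NULL` they are estimated from the window.
#' @param J GL truncation depth (default 50; >= 99% of the coefficient mass
#'   for orders up to ~1 at this depth).
#' @param alpha_levels Haar levels for internal alpha estimation.
#' @param refine_alpha After the first fit, re-invert each channel's raw
#'   Haar slope through the slope map conditioned on its fitted
#'   self-coupling `A[i,i]` (see `.haar_slope_damped`) and refit once.
#'   Removes the downward alpha bias a damped channel's flattened
#'   low-frequency spectrum induces; only applies when `alpha` is
#'   estimated internally.
#' @param tol Relative Frobenius change in `A` below which alternation stops.
#' @return An object of class `fodn_model`: list with `A`, `U`, `alpha`,
#'   `residuals`, `resid_fro` and `objective` traces, penalties, and `J`.
#' @export
fit_fodn <- function(X, lambda_ridge = NULL, lambda_lasso = NULL,
                     n_alt_iters = 3L, alpha = NULL, J = 50L,
                     alpha_levels = 4L, refine_alpha = FALSE, tol = 1e-6,
                     .Zfull = NULL) {
  X <- as.matrix(X)
  N <- nrow(X)
  n <- ncol(X)
  J <- .assert_count(J, "J", min = 1L)
  if (N <= J + 1L) stop("window shorter than GL truncation depth", call. = FALSE)
  raw_slope <- NULL
  if (is.null(alpha)) {
    est0 <- .alpha_matrix(X, alpha_levels)
    alpha <- est0$alpha
    raw_slope <- est0$slope
    alpha[!is.finite(alpha)] <- 0
  }
  if (length(alpha) != n) stop("`alpha` must have one entry per channel", call. = FALSE)
  m <- N - J                                    # usable regression samples
  if (m - 1L < 2L * n) {
    warning(sprintf("only %d usable time steps for %d channels; estimates may be unstable",
                    m - 1L, n), call. = FALSE)
  }
  # pairs: z[k] against x[k-1], k = J+2 ... N (so x[k-1] is itself on the
  # fully initialised range)
  Xm <- t(X[(J + 1L):(N - 1L), , drop = FALSE]) # n x (m-1)
  XXt <- tcrossprod(Xm)
  if (is.null(lambda_ridge)) lambda_ridge <- 0.1 * mean(diag(XXt))
  if (lambda_ridge < 0) stop("`lambda_ridge` must be >= 0", call. = FALSE)
  G <- XXt + diag(lambda_ridge, n)
  Gi <- tryCatch(chol2inv(chol(G)), error = function(e) NULL)
  if (is.null(Gi)) {
    stop("X X^T + lambda I is singular; use lambda_ridge > 0", call. = FALSE)
  }
  ridge_solve <- function(Zeff) t(Gi %*% tcrossprod(Xm, Zeff))
  fit_with_alpha <- function(alpha, Zpre = NULL) {
    Zfull <- if (!is.null(Zpre)) Zpre
             else .gl_derivative_matrix(X, alpha, J)  # rows k = J+1 ... N
    Zm <- t(Zfull[-1L, , drop = FALSE])           # n x (m-1)
    A <- ridge_solve(Zm)
    R0 <- Zm - A %*% Xm
    ll <- lambda_lasso
    if (is.null(ll)) {
      ll <- 2 * stats::mad(R0, center = 0)
      if (!is.finite(ll) || ll == 0) ll <- 0
    }
    soft <- function(R) sign(R) * pmax(abs(R) - ll, 0)
    objective <- function(A, U) {
      sum((Zm - A %*% Xm - U)^2) + lambda_ridge * sum(A^2) + 2 * ll * sum(abs(U))
    }
    U <- soft(R0)
    obj <- objective(A, U)
    resid_fro <- sqrt(sum((Zm - A %*% Xm - U)^2))
    n_iter <- 0L
    for (it in seq_len(n_alt_iters)) {
      A_new <- ridge_solve(Zm - U)
      U <- soft(Zm - A_new %*% Xm)
      obj_new <- objective(A_new, U)
      if (obj_new > obj[length(obj)] + 1e-8 * (1 + abs(obj[1L]))) {
        stop("internal error: alternation objective increased", call. = FALSE)
      }
      obj <- c(obj, obj_new)
      resid_fro <- c(resid_fro, sqrt(sum((Zm - A_new %*% Xm - U)^2)))
      dA <- sqrt(sum((A_new - A)^2)) / max(sqrt(sum(A^2)), 1e-12)
      A <- A_new
      n_iter <- it
      if (dA < tol) break
    }
    structure(list(A = A, B = "identity", U = U, alpha = alpha,
                   residuals = Zm - A %*% Xm - U,
                   resid_fro = resid_fro, objective = obj,
                   lambda_ridge = lambda_ridge, lambda_lasso = ll,
                   n_iter = n_iter, J = J),
              class = "fodn_model")
  }
  res <- fit_with_alpha(alpha, Zpre = .Zfull)
  if (refine_alpha && !is.null(raw_slope)) {
    # second pass: re-invert each channel's raw Haar slope through the
    # slope map conditioned on its fitted self-coupling, then refit
    agrid <- seq(-0.45, 1.45, by = 0.1)
    alpha_ref <- alpha
    for (i in seq_len(n)) {
      if (!is.finite(raw_slope[i])) next
      smap <- .haar_slope_damped(agrid, diag(res$A)[i], alpha_levels, J)
      alpha_ref[i] <- stats::approx(smap, agrid, xout = raw_slope[i], rule = 2)$y
    }
    res <- fit_with_alpha(alpha_ref)
  }
  res
}

#' Dominant eigenmode of a coupling matrix
#'
#' Selects the eigenvalue of largest modulus of `A` (ties broken towards the
#' first as returned by the decreasing-modulus eigen sort, deterministically)
#' and summarises its eigenvector as a real, unit-norm spatial weight
#' vector: for a real eigenpair the entries' absolute values after fixing
#' the sign of the largest-magnitude entry positive; for a complex pair the
#' componentwise modulus (which preserves the unit 2-norm).
#'
#' @param A Square, finite numeric matrix.
#' @return Object of class `eigenmode`: list with `lambda` (complex),
#'   `lambda_mod`, `lambda_phase`, `vector` (possibly complex, unit norm,
#'   rotated so its largest entry is real positive), `weights` (real,
#'   unit norm), `max_weight`, and `participation` (participation ratio
#'   `1 / (n sum w_i^4)`, 1 for a fully distributed mode, `1/n` for a
#'   single-channel mode).
#' @export
dominant_eigvec <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("`A` must be square", call. = FALSE)
  if (any(!is.finite(A))) stop("`A` contains non-finite entries", call. = FALSE)
  e <- eigen(A)
  lam <- e$values[1L]                 # eigen sorts by decreasing modulus
  v <- e$vectors[, 1L]
  v <- v / sqrt(sum(Mod(v)^2))
  i0 <- which.max(Mod(v))
  if (Mod(v[i0]) > 0) v <- v * Conj(v[i0]) / Mod(v[i0])  # largest entry real, positive
  if (all(Im(v) == 0) && is.complex(v)) v <- Re(v)
  w <- Mod(v)
  n <- length(w)
  structure(list(lambda = lam, lambda_mod = Mod(lam), lambda_phase = Arg(lam),
                 vector = v, weights = w, max_weight = max(w),
                 participation = 1 / (n * sum(w^4))),
            class = "eigenmode")
}

#' Windowed FODN identification over a trial
#'
#' Fits one FODN per analysis window and collects the per-window fractional
#' orders and dominant-eigenmode weights as channels x windows tracks (the
#' source arrays for alpha/eigenvector heatmaps), plus per-window spectral
#' summaries and the mean cosine similarity between consecutive windows'
#' weight vectors (mode stability).
#'
#' @param rec An `ad_recording` (see [recording()]).
#' @param grid A window grid from [make_windows()].
#' @param lambda_ridge,lambda_lasso,n_alt_iters,alpha,J,alpha_levels Passed
#'   to [fit_fodn()].
#' @param store_models Keep the full per-window model objects (default
#'   FALSE; the tracks are usually all that is needed).
#' @return Object of class `fodn_track`: list with `alpha_track` and
#'   `eig_track` (channels x windows), `lambda_mod`, `spectral_radius`,
#'   `max_weight`, `participation` (per window), `cos_stability`, `flagged`
#'   (windows that failed to fit), and optionally `models`.
#' @export
windowed_fodn <- function(rec, grid, lambda_ridge = NULL, lambda_lasso = NULL,
                          n_alt_iters = 3L, alpha = NULL, J = 50L,
                          alpha_levels = 4L, store_models = FALSE) {
  stopifnot(inherits(rec, "ad_recording"))
  nw <- nrow(grid)
  nch <- ncol(rec$signals)
  alpha_track <- matrix(NA_real_, nch, nw)
  eig_track <- matrix(NA_real_, nch, nw)
  lambda_mod <- spectral_radius <- max_weight <- participation <- rep(NA_real_, nw)
  flagged <- logical(nw)
  models <- if (store_models) vector("list", nw) else NULL
  rownames(alpha_track) <- rownames(eig_track) <- rec$channel_labels
  alpha_all <- NULL
  if (is.null(alpha) && nw > 0L) {
    # estimate every (window, channel) order in one batched Haar pass
    wlen <- grid$end_sample[1L] - grid$start_sample[1L]
    Xall <- matrix(0, wlen, nch * nw)
    for (w in seq_len(nw)) {
      rows <- (grid$start_sample[w] + 1L):grid$end_sample[w]
      Xall[, (w - 1L) * nch + seq_len(nch)] <- rec$signals[rows, , drop = FALSE]
    }
    alpha_all <- matrix(.alpha_matrix(Xall, alpha_levels)$alpha, nch, nw)
    alpha_all[!is.finite(alpha_all)] <- 0
    Zall <- .gl_derivative_matrix(Xall, as.vector(alpha_all), J)
  }
  for (w in seq_len(nw)) {
    rows <- (grid$start_sample[w] + 1L):grid$end_sample[w]
    fit <- tryCatch(
      fit_fodn(rec$signals[rows, , drop = FALSE], lambda_ridge = lambda_ridge,
               lambda_lasso = lambda_lasso, n_alt_iters = n_alt_iters,
               alpha = if (is.null(alpha_all)) alpha else alpha_all[, w],
               J = J, alpha_levels = alpha_levels,
               .Zfull = if (is.null(alpha_all)) NULL
                        else Zall[, (w - 1L) * nch + seq_len(nch), drop = FALSE]),
      error = function(e) NULL)
    if (is.null(fit)) { flagged[w] <- TRUE; next }
    em <- dominant_eigvec(fit$A)
    alpha_track[, w] <- fit$alpha
    eig_track[, w] <- em$weights
    lambda_mod[w] <- em$lambda_mod
    spectral_radius[w] <- em$lambda_mod   # = max modulus over the spectrum
    max_weight[w] <- em$max_weight
    participation[w] <- em$participation
    if (store_models) models[[w]] <- fit
  }
  ok <- which(!flagged)
  cosv <- NA_real_
  if (length(ok) >= 2L) {
    pairs <- ok[-length(ok)][diff(ok) == 1L]
    if (length(pairs)) {
      cosv <- mean(vapply(pairs, function(w) {
        a <- eig_track[, w]; b <- eig_track[, w + 1L]
        sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      }, numeric(1)))
    }
  }
  structure(list(alpha_track = alpha_track, eig_track = eig_track,
                 lambda_mod = lambda_mod, spectral_radius = spectral_radius,
                 max_weight = max_weight, participation = participation,
                 cos_stability = cosv, flagged = flagged, models = models),
            class = "fodn_track")
}
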