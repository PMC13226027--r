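#' Scaling-analysis configuration
#'
#' Segment lengths, detrending order and moment grid for DFA / MFDFA. The
#' default scales 16, 32, 64, 128 (2^4 ... 2^7) suit the short 500 ms
#' analysis windows; first-order (linear) polynomial detrending; moment
#' orders -5 ... 5. Fits use log base 2 (any base yields identical slopes).
#'
#' @param scales Segment lengths `s` for the fluctuation function.
#' @param detrend_order Polynomial detrending order (default 1).
#' @param q_grid Moment orders for MFDFA; must contain 2 (so `h(2)` is
#'   always available as the monofractal reference).
#' @param log_base Base of the log-log fit (slopes are base-invariant).
#' @return Object of class `scaling_config`.
#' @export
scaling_config <- function(scales = c(16L, 32L, 64L, 128L), detrend_order = 1L,
                           q_grid = c(-5:-1, 0, 1:5), log_base = 2) {
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 3L) stop("need at least 3 scales for the fit", call. = FALSE)
  if (min(scales) < detrend_order + 2L) {
    stop("min(scales) must be >= detrend_order + 2", call. = FALSE)
  }
  if (!2 %in% q_grid) stop("`q_grid` must contain 2", call. = FALSE)
  structure(list(scales = scales, detrend_order = as.integer(detrend_order),
                 q_grid = sort(unique(q_grid)), log_base = log_base),
            class = "scaling_config")
}

#' Profile (integrated series) of a signal
#'
#' Cumulative sum of the mean-removed signal, `Y(i) = sum_{k<=i} (x_k - xbar)`.
#' By telescoping, the final value is 0 up to float round-off.
#'
#' @param x Numeric vector, length >= 2, finite.
#' @return Numeric vector of the same length.
#' @export
dfa_profile <- function(x) {
  if (length(x) < 2L) stop("signal must have length >= 2", call. = FALSE)
  if (any(!is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  cumsum(x - mean(x))
}

#' Detrended variance of one profile segment
#'
#' Mean squared residual of an order-`order` polynomial least-squares fit
#' over segment `nu` (1-based, counted from the start of the profile) of
#' length `s`.
#'
#' @param Y Profile from [dfa_profile()].
#' @param s Segment length.
#' @param nu Segment index, `1 ... floor(length(Y)/s)`.
#' @param order Polynomial order (default 1).
#' @return `F^2(nu, s)`, a nonnegative scalar.
#' @export
detrended_variance <- function(Y, s, nu, order = 1L) {
  if (s <= order + 1L) stop("`s` must exceed order + 1", call. = FALSE)
  if (nu < 1L || nu * s > length(Y)) stop("segment outside profile", call. = FALSE)
  seg <- Y[((nu - 1L) * s + 1L):(nu * s)]
  H <- outer(seq_len(s) / s, 0:order, `^`)
  mean(stats::lm.fit(H, seg)$residuals^2)
}

# Residual-maker matrix for polynomial detrending over s samples.
.detrend_projector <- function(s, order) {
  H <- outer(seq_len(s) / s, 0:order, `^`)   # scaled abscissa for conditioning
  diag(s) - H %*% solve(crossprod(H), t(H))
}

# Segmentwise detrended variances of the columns of a profile matrix `Y`
# (N x m). Returns, per scale, the Ns x m forward and backward matrices of
# F^2(nu, s). Cached projectors keep repeated window scans cheap.
.f2_by_scale <- function(Y, scales, order) {
  N <- nrow(Y)
  m <- ncol(Y)
  lapply(scales, function(s) {
    Ns <- N %/% s
    if (Ns < 1L) return(list(fwd = NULL, bwd = NULL, Ns = 0L))
    if (order == 1L) {
      # closed-form linear detrend from segment moments: O(s) per segment
      i <- seq_len(s)
      ic <- i - mean(i)
      Sxx <- sum(ic^2)
      seg_f2 <- function(rows) {
        seg <- matrix(Y[rows, ], nrow = s)   # s x (Ns*m), column-major blocks
        Sy <- colSums(seg)
        Syy <- colSums(seg^2)
        b <- crossprod(ic, seg)[1L, ] / Sxx
        ss <- pmax(Syy - Sy^2 / s - b^2 * Sxx, 0)
        matrix(ss / s, nrow = Ns, ncol = m)
      }
    } else {
      M <- .detrend_projector(s, order)
      seg_f2 <- function(rows) {
        seg <- matrix(Y[rows, ], nrow = s)
        matrix(colMeans((M %*% seg)^2), nrow = Ns, ncol = m)
      }
    }
    fwd <- seg_f2(seq_len(Ns * s))
    bwd <- seg_f2((N - Ns * s + 1L):N)
    list(fwd = fwd, bwd = bwd, Ns = Ns)
  })
}

# Usable-channel mask and per-scale detrended variances for one window,
# shared between the DFA and MFDFA cores so a combined scan computes the
# profile and segment fits once.
.window_f2 <- function(X, config) {
  X <- as.matrix(X)
  fin <- colSums(!is.finite(X)) == 0
  v <- colMeans(X^2) - colMeans(X)^2
  ok <- fin & is.finite(v) & v > 0
  f2 <- NULL
  if (any(ok)) {
    Xo <- X[, ok, drop = FALSE]
    Y <- apply(sweep(Xo, 2L, colMeans(Xo)), 2L, cumsum)
    if (!is.matrix(Y)) Y <- matrix(Y, ncol = sum(ok))
    f2 <- .f2_by_scale(Y, config$scales, config$detrend_order)
  }
  list(ok = ok, f2 = f2)
}

# Core batched DFA: X is window data (samples x channels). Returns H and r2
# per channel plus the F(s) matrix (scales x channels). Channels with zero
# variance or non-finite samples come back NA (flagged).
.dfa_matrix <- function(X, config, pre = NULL) {
  X <- as.matrix(X)
  m <- ncol(X)
  if (is.null(pre)) pre <- .window_f2(X, config)
  ok <- pre$ok
  H <- r2 <- rep(NA_real_, m)
  Fs <- matrix(NA_real_, length(config$scales), m)
  if (any(ok)) {
    f2 <- pre$f2
    Fmat <- t(vapply(f2, function(l) {
      if (l$Ns < 1L) rep(NA_real_, sum(ok)) else sqrt(colMeans(l$fwd))
    }, numeric(sum(ok))))
    Fmat <- matrix(Fmat, nrow = length(config$scales))
    pos <- colSums(!is.finite(Fmat) | Fmat <= 0) == 0
    fit <- list(slope = rep(NA_real_, sum(ok)), r2 = rep(NA_real_, sum(ok)))
    if (any(pos)) {
      f <- .ls_slope(log(config$scales, config$log_base),
                     log(Fmat[, pos, drop = FALSE], config$log_base))
      fit$slope[pos] <- f$slope
      fit$r2[pos] <- f$r2
    }
    H[ok] <- fit$slope
    r2[ok] <- fit$r2
    Fs[, ok] <- Fmat
  }
  list(H = H, r2 = r2, Fs = Fs)
}

#' DFA Hurst exponent of a signal window
#'
#' Standard (monofractal) detrended fluctuation analysis: the profile is cut
#' into `Ns = floor(N/s)` non-overlapping forward segments per scale `s`,
#' locally detrended, and the fluctuation function
#' `F(s) = sqrt(mean F^2(nu, s))` is fitted as `F(s) ~ s^H` by least squares
#' on log-log axes.
#'
#' @param x Numeric signal; should be at least twice the largest scale.
#' @param config A [scaling_config()].
#' @return List with `H`, `fit_r2`, and the retained `Fs` values. A
#'   zero-variance or non-finite window gives `H = NA` (flagged), not an
#'   error.
#' @export
dfa_hurst <- function(x, config = scaling_config()) {
  res <- .dfa_matrix(matrix(as.numeric(x), ncol = 1L), config)
  list(H = res$H[1L], fit_r2 = res$r2[1L],
       Fs = stats::setNames(res$Fs[, 1L], config$scales))
}

# Core batched MFDFA. Both-ends segmentation (2 Ns segments per scale):
# Fq(s) = {(1/2Ns) sum_nu [F^2]^{q/2}}^{1/q}; q = 0 by logarithmic
# averaging, exp(mean(log F^2)/2). Zero-variance segments (F^2 = 0) are
# excluded for q <= 0 (they would blow up the negative moments); exclusion
# counts are reported.
.mfdfa_matrix <- function(X, config, pre = NULL) {
  X <- as.matrix(X)
  m <- ncol(X)
  q <- config$q_grid
  hq <- matrix(NA_real_, length(q), m, dimnames = list(q, colnames(X)))
  if (is.null(pre)) pre <- .window_f2(X, config)
  ok <- pre$ok
  n_zero_seg <- 0L
  if (any(ok)) {
    f2 <- pre$f2
    # Fq array: scales x q x channels
    Fq <- array(NA_real_, c(length(config$scales), length(q), sum(ok)))
    for (si in seq_along(config$scales)) {
      if (f2[[si]]$Ns < 1L) next
      F2 <- rbind(f2[[si]]$fwd, f2[[si]]$bwd)       # 2Ns x channels
      zero <- F2 <= 0
      n_zero_seg <- n_zero_seg + sum(zero)
      # F2^(q/2) for integer q via iterated products of the segment RMS
      # (much cheaper than pow on these large arrays)
      int_q <- all(q == round(q))
      if (int_q && length(q)) {
        r <- sqrt(F2)
        rneg <- ifelse(zero, NA, 1 / r)
        kmax <- max(abs(q))
        Ppos <- Pneg <- vector("list", kmax)
        if (kmax >= 1L) {
          Ppos[[1L]] <- r; Pneg[[1L]] <- rneg
          for (k in seq_len(kmax - 1L)) {
            Ppos[[k + 1L]] <- Ppos[[k]] * r
            Pneg[[k + 1L]] <- Pneg[[k]] * rneg
          }
        }
      }
      powq <- function(qq) {                         # F2^(qq/2) elementwise
        if (int_q) {
          if (qq > 0) Ppos[[qq]] else Pneg[[-qq]]
        } else if (qq > 0) F2^(qq / 2) else ifelse(zero, NA, F2^(qq / 2))
      }
      for (qi in seq_along(q)) {
        if (q[qi] == 0) {
          Fq[si, qi, ] <- exp(colMeans(log(ifelse(zero, NA, F2)), na.rm = TRUE) / 2)
        } else if (q[qi] > 0) {
          Fq[si, qi, ] <- colMeans(powq(q[qi]))^(1 / q[qi])
        } else {
          Fq[si, qi, ] <- colMeans(powq(q[qi]), na.rm = TRUE)^(1 / q[qi])
        }
      }
    }
    ls <- log(config$scales, config$log_base)
    hok <- matrix(NA_real_, length(q), sum(ok))
    for (qi in seq_along(q)) {
      lF <- log(matrix(Fq[, qi, ], nrow = length(config$scales)), config$log_base)
      good <- colSums(!is.finite(lF)) == 0
      if (any(good)) {
        hok[qi, good] <- .ls_slope(ls, lF[, good, drop = FALSE])$slope
      }
    }
    hq[, ok] <- hok
  }
  if (n_zero_seg > 0L) {
    warning(n_zero_seg, " zero-variance segment(s) excluded from negative-",
            "moment averages", call. = FALSE)
  }
  list(hq = hq, n_zero_segments = n_zero_seg)
}

#' Generalized Hurst exponents by multifractal DFA
#'
#' q-order fluctuation analysis over segments taken from both the start and
#' the end of the profile (2 Ns segments per scale):
#' `Fq(s) = ((1/2Ns) sum_nu [F^2(nu,s)]^{q/2})^{1/q}`, with the q -> 0 case
#' obtained by logarithmic averaging. `h(q)` is the per-q slope of
#' `log Fq(s)` against `log s`; dependence of `h` on `q` indicates
#' multifractality (for a monofractal signal `h(q)` is flat and equals the
#' DFA Hurst exponent up to the segmentation difference).
#'
#' @param x Numeric signal.
#' @param config A [scaling_config()].
#' @return List with `hq` (named by q), and `n_zero_segments` (segments
#'   excluded from negative moments).
#' @export
mfdfa_h <- function(x, config = scaling_config()) {
  res <- .mfdfa_matrix(matrix(as.numeric(x), ncol = 1L), config)
  list(hq = stats::setNames(res$hq[, 1L], rownames(res$hq)),
       n_zero_segments = res$n_zero_segments)
}

#' Windowed scaling scan of a trial
#'
#' Computes the DFA Hurst exponent and the MFDFA generalized Hurst exponents
#' of every channel in every window of a grid, plus per-channel time
#' averages (the quantities pooled across trials in the group comparison).
#'
#' @param rec An `ad_recording`.
#' @param grid An `ad_windows` grid from [make_windows()].
#' @param config A [scaling_config()].
#' @return Object of class `scaling_tracks`: list with `H` and `r2`
#'   (channels x windows), `hq` (q x channels x windows array), `gH`
#'   (channels x windows matrix of `h(2)`), `H_channel_mean`,
#'   `gH_channel_mean` (per-channel means over non-flagged windows), and
#'   `n_flagged` (count of channel-window cells without an estimate).
#' @export
windowed_scan <- function(rec, grid, config = scaling_config()) {
  stopifnot(inherits(rec, "ad_recording"))
  nw <- nrow(grid)
  nch <- ncol(rec$signals)
  q <- config$q_grid
  H <- r2 <- gH <- matrix(NA_real_, nch, nw,
                          dimnames = list(rec$channel_labels, NULL))
  hq <- array(NA_real_, c(length(q), nch, nw),
              dimnames = list(q, rec$channel_labels, NULL))
  wmax <- max(grid$end_sample - grid$start_sample, 0L)
  if (nw > 0L && max(config$scales) > wmax / 2) {
    warning("largest scale exceeds half the window length; the fit rests on ",
            "very few segments there", call. = FALSE)
  }
  if (nw > 0L) {
    # batch every (window, channel) pair as one column so the profile,
    # detrending and moment sums run as a few large matrix operations
    wlen <- grid$end_sample[1L] - grid$start_sample[1L]
    Xall <- matrix(0, wlen, nch * nw)
    for (w in seq_len(nw)) {
      rows <- (grid$start_sample[w] + 1L):grid$end_sample[w]
      Xall[, (w - 1L) * nch + seq_len(nch)] <- rec$signals[rows, , drop = FALSE]
    }
    pre <- .window_f2(Xall, config)
    d <- .dfa_matrix(Xall, config, pre)
    mf <- suppressWarnings(.mfdfa_matrix(Xall, config, pre))
    H[] <- d$H
    r2[] <- d$r2
    hq[] <- mf$hq
    gH[] <- mf$hq[match(2, q), ]
  }
  structure(list(H = H, r2 = r2, hq = hq, gH = gH,
                 H_channel_mean = rowMeans(H, na.rm = TRUE),
                 gH_channel_mean = rowMeans(gH, na.rm = TRUE),
                 n_flagged = sum(is.na(H))),
            class = "scaling_tracks")
}

#' Tidy long-format export of a scaling track
#'
#' @param tracks A `scaling_tracks` object.
#' @param trial_id Identifier to stamp on every row.
#' @param segment Phase label (`"W1"`/`"W2"`).
#' @return data.frame with columns `trial`, `segment`, `channel`,
#'   `window_index`, `H`, `gH`.
#' @export
tracks_to_df <- function(tracks, trial_id = "t01", segment = "W1") {
  nch <- nrow(tracks$H)
  nw <- ncol(tracks$H)
  data.frame(trial = trial_id, segment = segment,
             channel = rep(rownames(tracks$H), nw),
             window_index = rep(seq_len(nw), each = nch),
             H = as.vector(tracks$H), gH = as.vector(tracks$gH))
}
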