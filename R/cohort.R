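#' Specification of a synthetic after-discharge trial cohort
#'
#' Parameters of the synthetic cohort generator. The defaults mirror the
#' structure of a multi-patient functional-mapping series: 43 stimulation
#' trials of which 20 end in successful suppression, 1000 Hz sampling, and
#' around 60 retained channels per trial. Channel backgrounds are
#' long-memory (ARFIMA) processes whose fractional order is redrawn every
#' 500 ms from phase-specific distributions; successful trials tighten that
#' distribution (and damp the after-discharge spikes) during W2 in
#' proportion to `effect_delta`, so the injected signature is reduced
#' variability of the scaling exponents -- the pattern the analysis is built
#' to detect. `effect_delta = 0` yields a null cohort in which success and
#' failure trials are statistically exchangeable.
#'
#' @param n_trials,n_success Trial counts (`n_success <= n_trials`).
#' @param n_channels Channels per trial.
#' @param fs_hz Sampling rate (Hz).
#' @param w1_duration_s,w2_duration_s Phase duration ranges in seconds
#'   (each trial draws uniformly within the range); all durations > 1 s.
#' @param alpha_mean_w1,alpha_sd_w1 Mean and spread of the per-block
#'   channel fractional orders during W1 (and during W2 of failed trials).
#' @param alpha_mean_w2_success,alpha_sd_w2_success Same for W2 of fully
#'   successful trials (`effect_delta = 1`).
#' @param spike_rate_hz After-discharge transient rate (2-4 Hz is typical).
#' @param spike_amp Peak amplitude of the biphasic transients, in units of
#'   the unit-variance background.
#' @param effect_delta Dimensionless suppression effect size; 0 = null
#'   cohort, 1 = full effect.
#' @param coupling_rho Spectral radius of each trial's planted coupling
#'   matrix.
#' @param seed RNG seed for the whole cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_trials = 43L, n_success = 20L, n_channels = 60L,
                        fs_hz = 1000, w1_duration_s = c(3, 6),
                        w2_duration_s = c(4, 8),
                        alpha_mean_w1 = 0.30, alpha_sd_w1 = 0.12,
                        alpha_mean_w2_success = 0.18,
                        alpha_sd_w2_success = 0.04,
                        spike_rate_hz = 3, spike_amp = 2,
                        effect_delta = 1, coupling_rho = 0.35, seed = NULL) {
  n_trials <- .assert_count(n_trials, "n_trials")
  n_success <- .assert_count(n_success, "n_success", min = 0L)
  n_channels <- .assert_count(n_channels, "n_channels", min = 2L)
  if (n_success > n_trials) stop("n_success must be <= n_trials", call. = FALSE)
  if (fs_hz <= 0) stop("fs_hz must be > 0", call. = FALSE)
  if (min(w1_duration_s) <= 1 || min(w2_duration_s) <= 1) {
    stop("all phase durations must exceed 1 s", call. = FALSE)
  }
  if (effect_delta < 0) stop("effect_delta must be >= 0", call. = FALSE)
  if (spike_rate_hz <= 0 || spike_rate_hz > fs_hz / 10) {
    stop("infeasible spike rate", call. = FALSE)
  }
  structure(list(n_trials = n_trials, n_success = n_success,
                 n_channels = n_channels, fs_hz = fs_hz,
                 w1_duration_s = w1_duration_s, w2_duration_s = w2_duration_s,
                 alpha_mean_w1 = alpha_mean_w1, alpha_sd_w1 = alpha_sd_w1,
                 alpha_mean_w2_success = alpha_mean_w2_success,
                 alpha_sd_w2_success = alpha_sd_w2_success,
                 spike_rate_hz = spike_rate_hz, spike_amp = spike_amp,
                 effect_delta = effect_delta, coupling_rho = coupling_rho,
                 seed = seed),
            class = "cohort_spec")
}

# Long-memory background for one contiguous segment: per channel, the
# fractional order is redrawn every `block_s` seconds from N(mean, sd)
# (clipped to the stationary ARFIMA range) and each block is generated by
# the batched fractional filter, normalised to unit variance.
.segment_background <- function(n_samples, n_channels, fs_hz, a_mean, a_sd,
                                block_s = 0.5, L = 256L) {
  if (n_samples < 1L) {
    return(list(x = matrix(0, 0L, n_channels), d = matrix(0, 0L, n_channels)))
  }
  blen <- max(2L, round(block_s * fs_hz))
  nblocks <- ceiling(n_samples / blen)
  # one batched fractional filter over all (block, channel) columns
  d <- pmin(pmax(stats::rnorm(nblocks * n_channels, a_mean, a_sd), -0.45), 0.45)
  dmat <- matrix(d, nblocks, n_channels, byrow = TRUE)
  eps <- matrix(stats::rnorm((blen + L) * nblocks * n_channels),
                ncol = nblocks * n_channels)
  xb <- .arfima_filter(eps, as.vector(t(dmat)), blen, L)
  sds <- sqrt(pmax(colMeans(xb^2) - colMeans(xb)^2, 0))
  sds[sds == 0] <- 1
  xb <- sweep(xb, 2L, sds, `/`)
  # columns are (block 1: ch 1..n, block 2: ch 1..n, ...) -> stack blocks in time
  out <- matrix(0, nblocks * blen, n_channels)
  for (b in seq_len(nblocks)) {
    out[((b - 1L) * blen + 1L):(b * blen), ] <-
      xb[, (b - 1L) * n_channels + seq_len(n_channels), drop = FALSE]
  }
  list(x = out[seq_len(n_samples), , drop = FALSE], d = dmat)
}

# Biphasic spike kernel: one sine cycle under a Hann taper, ~60 ms.
.spike_kernel <- function(fs_hz, dur_s = 0.06) {
  n <- max(4L, round(dur_s * fs_hz))
  t <- seq_len(n) / n
  sin(2 * pi * t) * 0.5 * (1 - cos(2 * pi * t))
}

#' Generate a synthetic trial cohort
#'
#' Builds `n_trials` multichannel recordings with event timelines and
#' ground truth. Each trial is a channelwise long-memory (ARFIMA)
#' background with block-varying fractional order, mixed through a planted
#' sparse directed coupling matrix (`x[k] = A x[k-1] + background[k]`),
#' with periodic biphasic spike transients throughout the after-discharge
#' period. During W2 of successful trials the fractional-order
#' distribution tightens and the spike amplitude is damped, both scaled by
#' `effect_delta`. Roughly every third trial carries intermediate
#' behavioural markers (`Qes_End`, `Ans_Start`, `Ans_End`) inside W2, which
#' exercise the marker-restart behaviour of the window grids.
#'
#' @param spec A [cohort_spec()].
#' @return List of trials; each element has `recording` (`ad_recording`),
#'   `timeline` (`ad_timeline`) and `truth` (planted `A`, per-block
#'   fractional orders per phase, spike schedule, outcome label).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    fs <- spec$fs_hz
    nch <- spec$n_channels
    outcomes <- sample(c(rep("success", spec$n_success),
                         rep("failure", spec$n_trials - spec$n_success)))
    delta <- min(spec$effect_delta, 1)
    m2 <- spec$alpha_mean_w1 + delta * (spec$alpha_mean_w2_success - spec$alpha_mean_w1)
    s2 <- spec$alpha_sd_w1 + delta * (spec$alpha_sd_w2_success - spec$alpha_sd_w1)
    spike_scale_w2 <- 1 - 0.8 * delta
    kern <- .spike_kernel(fs)
    lapply(seq_len(spec$n_trials), function(tr) {
      w1 <- stats::runif(1, spec$w1_duration_s[1L], spec$w1_duration_s[2L])
      w2 <- stats::runif(1, spec$w2_duration_s[1L], spec$w2_duration_s[2L])
      pre <- 0.25; post <- 0.25
      ad_start <- pre; qes_start <- pre + w1; ad_end <- pre + w1 + w2
      total_n <- round((ad_end + post) * fs)
      succ <- outcomes[tr] == "success"
      a2 <- if (succ) c(m2, s2) else c(spec$alpha_mean_w1, spec$alpha_sd_w1)
      segs <- list(
        list(n = round(ad_start * fs), par = c(spec$alpha_mean_w1, spec$alpha_sd_w1)),
        list(n = round(qes_start * fs) - round(ad_start * fs),
             par = c(spec$alpha_mean_w1, spec$alpha_sd_w1)),
        list(n = round(ad_end * fs) - round(qes_start * fs), par = a2),
        list(n = total_n - round(ad_end * fs),
             par = c(spec$alpha_mean_w1, spec$alpha_sd_w1)))
      bg <- lapply(segs, function(sg) {
        .segment_background(sg$n, nch, fs, sg$par[1L], sg$par[2L])
      })
      S <- do.call(rbind, lapply(bg, `[[`, "x"))
      truth_net <- random_fodn_truth(nch, rho = spec$coupling_rho,
                                     check = "spectral")
      # one-step coupling: x[k] = A x[k-1] + background[k]
      X <- t(S)
      for (k in 2:ncol(X)) X[, k] <- truth_net$A %*% X[, k - 1L] + X[, k]
      X <- t(X)
      # after-discharge spike transients across [AD_Start, AD_End)
      amp <- spec$spike_amp * (stats::runif(nch) < 0.4) * stats::runif(nch, 0.5, 1)
      times <- seq(ad_start, ad_end - 0.1, by = 1 / spec$spike_rate_hz)
      times <- times + stats::runif(length(times), -0.02, 0.02)
      spike_sched <- data.frame(time_s = times,
                                scale = ifelse(times >= qes_start & succ,
                                               spike_scale_w2, 1))
      for (i in seq_len(nrow(spike_sched))) {
        idx0 <- round(spike_sched$time_s[i] * fs)
        idx <- idx0 + seq_along(kern)
        idx_ok <- idx >= 1L & idx <= nrow(X)
        X[idx[idx_ok], ] <- X[idx[idx_ok], ] +
          outer(kern[idx_ok], amp * spike_sched$scale[i])
      }
      rec <- recording(X, fs_hz = fs,
                       patient_id = sprintf("p%02d", 1L + (tr - 1L) %/% 4L),
                       trial_id = sprintf("t%02d", tr), outcome = outcomes[tr])
      ev_names <- c("AD_Start", "Qes_Start", "AD_End")
      ev_times <- c(ad_start, qes_start, ad_end)
      if (tr %% 3L == 0L && w2 > 4) {
        ev_names <- c(ev_names, "Qes_End", "Ans_Start", "Ans_End")
        ev_times <- c(ev_times, qes_start + 1.0, qes_start + 1.5, qes_start + 2.5)
      }
      tl <- timeline(ev_names, ev_times, rec = rec)
      truth <- list(A = truth_net$A, alpha_w1 = bg[[2L]]$d, alpha_w2 = bg[[3L]]$d,
                    u = spike_sched, spike_amp = amp, outcome = outcomes[tr])
      list(recording = rec, timeline = tl, truth = truth)
    })
  })
}
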