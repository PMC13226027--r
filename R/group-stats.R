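#' Pool per-channel time-averaged exponents across trials
#'
#' One value per (trial, channel): the mean of that channel's window-level
#' exponents over the requested phase, with flagged (missing) windows
#' excluded. Pools over all trials of a given outcome class, giving the
#' phase distribution whose W1-vs-W2 shift the group comparison tests.
#'
#' @param trials A list of analysed trials as returned by [run_pipeline()]
#'   (`$trials`), each holding `scaling_tracks` per phase and an `outcome`.
#' @param phase `"W1"` or `"W2"`.
#' @param outcome `"success"` or `"failure"`.
#' @param what `"H"` (DFA Hurst) or `"gH"` (MFDFA `h(2)`).
#' @return Object of class `ad_pool`: data.frame with `trial`, `channel`,
#'   `value`; `n` = number of pooled channels is `nrow()`.
#' @export
pool_exponents <- function(trials, phase = c("W1", "W2"),
                           outcome = c("success", "failure"), what = "H") {
  phase <- match.arg(phase)
  outcome <- match.arg(outcome)
  keep <- Filter(function(tr) tr$outcome == outcome, trials)
  if (!length(keep)) stop("no trials with outcome ", outcome, call. = FALSE)
  rows <- lapply(keep, function(tr) {
    tk <- tr$phases[[phase]]$scaling
    vals <- if (what == "H") tk$H_channel_mean else tk$gH_channel_mean
    data.frame(trial = tr$trial_id, channel = names(vals), value = vals,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  dropped <- !is.finite(out$value)
  if (any(dropped)) {
    message(sum(dropped), " channel(s) fully flagged; excluded from pool")
    out <- out[!dropped, , drop = FALSE]
  }
  if (!nrow(out)) stop("empty pool", call. = FALSE)
  structure(out, class = c("ad_pool", "data.frame"),
            phase = phase, outcome = outcome)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sample p-value
#' (Kolmogorov distribution at effective size `n1 n2 / (n1 + n2)`), the
#' approximation appropriate at the pool sizes arising here. Raw p-values;
#' no multiple-testing correction is applied anywhere downstream.
#'
#' @param a,b Numeric samples (each nonempty).
#' @return Object of class `ks_result`: list with `D`, `p`, `n1`, `n2`.
#' @export
ks_two_sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(list(D = unname(ht$statistic), p = unname(ht$p.value),
                 n1 = length(a), n2 = length(b)),
            class = "ks_result")
}

#' Channel-by-channel W1 vs W2 comparison within one trial
#'
#' For every channel, the window-level exponents of W1 are compared with
#' those of W2 by the two-sample KS test. Channels with fewer than two
#' usable windows in either phase are flagged (`NA`) rather than tested.
#'
#' @param track_w1,track_w2 `scaling_tracks` for the two phases of one
#'   trial.
#' @param what `"H"` or `"gH"`.
#' @return data.frame with `channel`, `D`, `p`, `n1`, `n2`, `flagged`.
#' @export
channelwise_ks <- function(track_w1, track_w2, what = "H") {
  M1 <- if (what == "H") track_w1$H else track_w1$gH
  M2 <- if (what == "H") track_w2$H else track_w2$gH
  stopifnot(nrow(M1) == nrow(M2))
  res <- lapply(seq_len(nrow(M1)), function(ch) {
    a <- M1[ch, ]; a <- a[is.finite(a)]
    b <- M2[ch, ]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) {
      return(data.frame(channel = rownames(M1)[ch], D = NA_real_, p = NA_real_,
                        n1 = length(a), n2 = length(b), flagged = TRUE))
    }
    ks <- ks_two_sample(a, b)
    data.frame(channel = rownames(M1)[ch], D = ks$D, p = ks$p,
               n1 = ks$n1, n2 = ks$n2, flagged = FALSE)
  })
  do.call(rbind, res)
}
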