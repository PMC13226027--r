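# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# A small but non-degenerate cohort: enough trials for LOOCV, short phases
# and few channels so the full pipeline stays fast in unit tests.
small_cohort_spec <- function(seed = 42L) {
  cohort_spec(n_trials = 10L, n_success = 5L, n_channels = 12L,
              w1_duration_s = c(3, 4), w2_duration_s = c(4, 5), seed = seed)
}

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- gen_cohort(small_cohort_spec())
  }
  .fixture_env$cohort
}

small_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- run_pipeline(small_cohort(), pipeline_config(seed = 7L))
  }
  .fixture_env$run
}

# Naive textbook DFA, O(N * s) with explicit per-segment lm fits: the
# independent oracle the fast implementation is checked against.
naive_dfa <- function(x, scales = c(16L, 32L, 64L, 128L), order = 1L) {
  Y <- cumsum(x - mean(x))
  Fs <- vapply(scales, function(s) {
    Ns <- length(Y) %/% s
    f2 <- vapply(seq_len(Ns), function(nu) {
      seg <- Y[((nu - 1L) * s + 1L):(nu * s)]
      i <- seq_len(s)
      mean(stats::lm(seg ~ stats::poly(i, order, raw = TRUE))$residuals^2)
    }, numeric(1))
    sqrt(mean(f2))
  }, numeric(1))
  unname(stats::coef(stats::lm(log2(Fs) ~ log2(scales)))[2L])
}

# Direct Gamma-formula GL coefficients through log-gamma arithmetic
# (independent of the package's recursion). For fractional alpha in (0, 1):
# Gamma(-alpha) < 0 and Gamma(j - alpha) < 0 only at j = 0, so the ratio's
# sign is +1 at j = 0 and -1 beyond; integer alpha uses the binomial form.
gl_coef_gamma <- function(alpha, J) {
  j <- 0:J
  if (alpha == round(alpha) && alpha >= 0) return((-1)^j * choose(alpha, j))
  stopifnot(alpha > 0, alpha < 1)
  sgn <- ifelse(j == 0L, 1, -1)
  sgn * exp(lgamma(j - alpha) - lgamma(-alpha) - lgamma(j + 1))
}
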