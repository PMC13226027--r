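test_that("fGn synthesis is deterministic under a seed and white at H = 0.5", {
  x1 <- gen_fgn(0.7, 512, seed = 3)
  x2 <- gen_fgn(0.7, 512, seed = 3)
  expect_identical(x1, x2)
  expect_false(identical(x1, gen_fgn(0.7, 512, seed = 4)))

  x <- gen_fgn(0.5, 4096, seed = 1)
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 3 / sqrt(4096))
  expect_error(gen_fgn(1.2, 512), "inside \\(0, 1\\)")
  expect_error(gen_fgn(0.5, 16), ">= 64")
})

test_that("fGn carries its nominal Hurst exponent through DFA", {
  est <- vapply(1:20, function(s) dfa_hurst(gen_fgn(0.8, 4096, seed = s))$H,
                numeric(1))
  expect_gte(mean(est), 0.70)
  expect_lte(mean(est), 0.90)
})

test_that("ARFIMA generator reduces to its driving noise at d = 0", {
  x <- gen_arfima(0, 1024, seed = 5)
  expect_equal(as.numeric(x), attr(x, "innovations"), tolerance = 1e-12)
  expect_error(gen_arfima(0.6, 256), "\\|d\\| < 0.5")
})

test_that("ARFIMA fractional order is recovered by the wavelet regression", {
  est <- vapply(1:20, function(s) {
    estimate_alpha(gen_arfima(0.4, 8192, seed = s), levels = 6)$alpha
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.4), 0.15)
  xneg <- gen_arfima(-0.3, 8192, seed = 9)
  expect_lt(estimate_alpha(xneg, levels = 6)$alpha, 0)
})

test_that("binomial cascade matches its closed-form exponent structure", {
  # a -> 0.5: h(q) -> 1 for every q
  expect_equal(cascade_hq(0.5 + 1e-9, c(-5, -1, 2, 5)), rep(1, 4),
               tolerance = 1e-6)
  # monotonicity: small fluctuations scale harder than large ones
  for (a in c(0.6, 0.75, 0.9)) {
    expect_gt(cascade_hq(a, -5), cascade_hq(a, 5))
  }
  x <- gen_binomial_cascade(0.75, 10)
  expect_length(x, 1024)
  expect_equal(sum(x), 1)             # mass conservation of the measure
  expect_error(gen_binomial_cascade(0.4, 8), "inside \\(0.5, 1\\)")
})

test_that("FODN simulation collapses to white noise without dynamics", {
  tr <- list(A = matrix(0, 3, 3), alpha = c(0, 0, 0), J = 20L)
  X <- simulate_fodn(tr, 2000, noise_sd = 1, seed = 2)
  expect_equal(dim(X), c(2000L, 3L))
  for (ch in 1:3) {
    r1 <- stats::cor(X[-1, ch], X[-2000, ch])
    expect_lt(abs(r1), 3 / sqrt(2000))
    expect_lt(abs(stats::sd(X[-1, ch]) - 1), 0.1)
  }
  expect_identical(X, simulate_fodn(tr, 2000, noise_sd = 1, seed = 2))
})

test_that("unstable coupling matrices are rejected with the offending eigenvalue", {
  tr <- list(A = diag(c(1.05, 0.2)), alpha = c(0.3, 0.3), J = 10L)
  expect_error(simulate_fodn(tr, 100), "modulus 1.05")
})

test_that("ground-truth networks are stable under the truncated-GL dynamics", {
  for (s in 1:3) {
    tr <- random_fodn_truth(8, seed = s)
    expect_lt(max(Mod(eigen(tr$A, only.values = TRUE)$values)), 1)
    X <- simulate_fodn(tr, 1500, noise_sd = 0.1, seed = 100 + s)
    expect_true(all(is.finite(X)))
    expect_lt(max(abs(X[1001:1500, ])), 50 * stats::sd(X[1:500, ]))
  }
})

test_that("cohort generator produces valid labelled recordings", {
  co <- small_cohort()
  expect_length(co, 10L)
  outcomes <- vapply(co, function(x) x$recording$outcome, character(1))
  expect_equal(sum(outcomes == "success"), 5L)
  sp <- cohort_spec()
  expect_equal(sp$n_trials, 43L)
  expect_equal(sp$n_success, 20L)
  for (tr in co[1:3]) {
    rec <- tr$recording
    expect_s3_class(rec, "ad_recording")
    expect_true(all(is.finite(rec$signals)))
    expect_equal(ncol(rec$signals), 12L)
    # timeline valid and phases non-empty
    seg <- trial_segments(rec, tr$timeline)
    expect_gt(seg$w1[2], seg$w1[1])
    expect_gt(seg$w2[2], seg$w2[1])
    # round-trips through the bundle format
    dir <- withr::local_tempdir()
    write_bundle(rec, tr$timeline, dir)
    back <- read_bundle(file.path(dir, paste0(rec$trial_id, ".tsv")))
    expect_equal(back$recording$signals, rec$signals, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(cohort_spec(n_trials = 5, n_success = 9), "n_success")
  expect_error(cohort_spec(w1_duration_s = c(0.5, 1)), "exceed 1 s")
})
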