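test_that("profile integrates the mean-removed signal", {
  expect_equal(dfa_profile(c(1, 2, 3)), c(-1, -1, 0))
  set.seed(1)
  x <- rnorm(1000, sd = 3)
  Y <- dfa_profile(x)
  expect_lt(abs(Y[length(Y)]), 1e-9 * length(x) * stats::sd(x))
  expect_equal(dfa_profile(rep(2.5, 50)), rep(0, 50))
  expect_error(dfa_profile(numeric(0)), "length >= 2")
})

test_that("detrended variance matches an explicit fit-then-variance oracle", {
  i <- 1:64
  expect_lt(detrended_variance(2 + 0.5 * i, 64, 1), 1e-20)
  expect_gt(detrended_variance(i^2, 64, 1), 0)
  set.seed(3)
  Y <- cumsum(rnorm(512))
  for (s in c(16L, 32L, 128L)) {
    for (nu in c(1L, 512L %/% s)) {
      seg <- Y[((nu - 1) * s + 1):(nu * s)]
      oracle <- mean(stats::lm(seg ~ seq_len(s))$residuals^2)
      expect_equal(detrended_variance(Y, s, nu), oracle, tolerance = 1e-12)
    }
  }
})

test_that("fast DFA agrees with the naive textbook implementation", {
  set.seed(7)
  for (rep in 1:50) {
    x <- rnorm(500) + if (rep %% 2) cumsum(rnorm(500, sd = 0.05)) else 0
    expect_equal(dfa_hurst(x)$H, naive_dfa(x), tolerance = 1e-10)
  }
})

test_that("DFA recovers white-noise scaling and is affine invariant", {
  est <- vapply(1:20, function(s) {
    set.seed(s); dfa_hurst(rnorm(4096))$H
  }, numeric(1))
  expect_gte(mean(est), 0.45)
  expect_lte(mean(est), 0.55)

  x <- gen_fgn(0.8, 4096, seed = 1)
  expect_lt(abs(dfa_hurst(x)$H - 0.8), 0.1)
  expect_equal(dfa_hurst(5 * x - 2)$H, dfa_hurst(x)$H, tolerance = 1e-12)

  flat <- dfa_hurst(rep(1, 500))
  expect_true(is.na(flat$H))
})

test_that("MFDFA is flat for monofractal input and consistent with DFA", {
  cfg <- scaling_config(scales = 2^(4:9))
  x <- gen_fgn(0.7, 2^13, seed = 11)
  h <- mfdfa_h(x, cfg)$hq
  expect_lte(max(h) - min(h), 0.15)
  # h(2) and the DFA exponent differ only by the both-ends segmentation
  win <- x[1:2000]
  expect_lt(abs(mfdfa_h(win)$hq[["2"]] - dfa_hurst(win)$H), 0.1)
})

test_that("zero-variance segments are excluded from negative moments, with warning", {
  x <- c(rep(0, 200), rnorm(300))
  expect_warning(res <- mfdfa_h(x), "zero-variance segment")
  expect_true(all(is.finite(res$hq[as.character(1:5)])))
})

test_that("windowed scan returns per-channel per-window tracks and averages", {
  co <- small_cohort()
  tr <- co[[1]]
  rec <- zscore_channels(tr$recording)
  grid <- make_windows(rec, tr$timeline, "W1", "nonoverlap")
  tk <- windowed_scan(rec, grid)
  expect_equal(dim(tk$H), c(12L, nrow(grid)))
  expect_equal(dim(tk$gH), c(12L, nrow(grid)))
  expect_equal(dim(tk$hq), c(11L, 12L, nrow(grid)))
  expect_length(tk$H_channel_mean, 12L)
  expect_true(all(is.finite(tk$H)))
  df <- tracks_to_df(tk, "t01", "W1")
  expect_equal(nrow(df), 12L * nrow(grid))

  # an all-constant channel is flagged missing, not fatal
  rec2 <- tr$recording
  rec2$signals[, 3] <- 0
  tk2 <- windowed_scan(rec2, grid)
  expect_true(all(is.na(tk2$H[3, ])))
  expect_true(all(is.finite(tk2$H[-3, ])))
  expect_equal(tk2$n_flagged, nrow(grid))
})

test_that("a 10 s two-phase 60-channel trial scans within the time budget", {
  set.seed(21)
  rec <- recording(matrix(rnorm(10500 * 60), 10500, 60), fs_hz = 1000)
  tl <- timeline(c("AD_Start", "Qes_Start", "AD_End"), c(0.25, 5.25, 10.25),
                 rec = rec)
  elapsed <- system.time({
    for (seg in c("W1", "W2")) {
      windowed_scan(rec, make_windows(rec, tl, seg, "nonoverlap"))
    }
  })["elapsed"]
  expect_lt(elapsed, 30)
})
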