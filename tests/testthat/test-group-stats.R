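test_that("pooling yields one value per trial-channel pair", {
  run <- small_run()
  p1 <- pool_exponents(run$trials, "W1", "success")
  expect_equal(nrow(p1), 5L * 12L)
  expect_true(all(is.finite(p1$value)))
  expect_error(pool_exponents(list(), "W1", "success"), "no trials")
})

test_that("suppression cohorts shrink the W2 exponent spread", {
  run <- small_run()
  p1 <- pool_exponents(run$trials, "W1", "success")
  p2 <- pool_exponents(run$trials, "W2", "success")
  expect_lt(stats::var(p2$value), stats::var(p1$value))
})

test_that("KS statistic honours its boundary cases and invariances", {
  a <- c(1, 2, 3, 4, 5)
  same <- ks_two_sample(a, a)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disj <- ks_two_sample(1:50, 101:150)
  expect_equal(disj$D, 1)
  expect_lt(disj$p, 1e-10)
  expect_error(ks_two_sample(numeric(0), a), "empty sample")

  set.seed(8)
  x <- rnorm(300); y <- rnorm(300, 0.3)
  base <- ks_two_sample(x, y)
  mono <- ks_two_sample(exp(x), exp(y))   # strictly monotone transform
  expect_equal(base$D, mono$D, tolerance = 1e-12)

  # p decreases as D grows at fixed sample sizes
  shifts <- c(0.1, 0.4, 0.8, 1.5)
  res <- lapply(shifts, function(s) ks_two_sample(x, x + s))
  Ds <- vapply(res, `[[`, numeric(1), "D")
  ps <- vapply(res, `[[`, numeric(1), "p")
  expect_true(all(diff(Ds) > 0))
  expect_true(all(diff(ps) < 0))
})

test_that("channelwise comparison flags thin channels and finds planted shifts", {
  set.seed(9)
  nch <- 30; nw <- 40
  mk <- function(shift_ch = NULL, delta = 0) {
    H <- matrix(rnorm(nch * nw, 1), nch, nw,
                dimnames = list(sprintf("ch%03d", 1:nch), NULL))
    if (!is.null(shift_ch)) H[shift_ch, ] <- H[shift_ch, ] + delta
    list(H = H, gH = H)
  }
  # null: rejection fraction compatible with the 5% level
  reject <- replicate(10, {
    res <- channelwise_ks(mk(), mk())
    mean(res$p < 0.05)
  })
  expect_lt(mean(reject), 0.05 + 3 * sqrt(0.05 * 0.95 / (10 * nch)))

  # a channel with a planted W2 shift has the smallest p-value
  res <- channelwise_ks(mk(), mk(shift_ch = 7, delta = 0.9))
  expect_equal(which.min(res$p), 7L)

  # single-window phase: flagged, not an error
  thin <- mk(); thin$H <- thin$H[, 1, drop = FALSE]; thin$gH <- thin$H
  res2 <- channelwise_ks(thin, mk())
  expect_true(all(res2$flagged))
  expect_true(all(is.na(res2$D)))
})
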