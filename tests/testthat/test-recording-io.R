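make_rec <- function(n = 4000, nch = 4, fs = 1000, seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(n * nch), n, nch), fs_hz = fs, trial_id = "t99")
}

std_tl <- function(rec, extra = NULL) {
  nm <- c("AD_Start", "Qes_Start", "AD_End")
  tt <- c(0.2, 1.2, 3.7)
  if (!is.null(extra)) { nm <- c(nm, names(extra)); tt <- c(tt, unname(extra)) }
  timeline(nm, tt, rec = rec)
}

test_that("timeline validation names the offending marker", {
  rec <- make_rec()
  expect_error(timeline(c("AD_Start", "Qes_Start"), c(0.1, 1)), "AD_End")
  expect_error(timeline(c("AD_Start", "Qes_Start", "AD_End"), c(1.2, 1.2, 3)),
               "not strictly increasing")
  expect_error(timeline(c("AD_Start", "Qes_Start", "AD_End"), c(0.5, 3, 1)),
               "out of order")
  expect_error(timeline(c("AD_Start", "Qes_Start", "AD_End"), c(0.5, 1, 99),
                        rec = rec), "outside the recording span")
  expect_error(timeline(c("AD_Start", "Bogus", "Qes_Start", "AD_End"),
                        c(0.1, 0.5, 1, 3)), "unknown marker")
})

test_that("bundles round-trip losslessly and honour channel exclusion", {
  rec <- make_rec()
  tl <- std_tl(rec)
  dir <- withr::local_tempdir()
  write_bundle(rec, tl, dir)
  back <- read_bundle(file.path(dir, "t99.tsv"))
  expect_equal(back$recording$signals, rec$signals, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$timeline$time_s, tl$time_s)
  expect_equal(back$recording$fs_hz, rec$fs_hz)

  write_bundle(rec, tl, dir, excluded_channels = c("ch001", "ch003"))
  back2 <- read_bundle(file.path(dir, "t99.tsv"))
  expect_equal(ncol(back2$recording$signals), 2L)
  expect_equal(back2$recording$channel_labels, c("ch002", "ch004"))

  # corrupt signals are a validation error naming the channel
  sig <- rec$signals; sig[10, 2] <- NA
  df <- as.data.frame(sig)
  utils::write.table(df, file.path(dir, "bad.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  file.copy(file.path(dir, "t99.meta.json"), file.path(dir, "bad.meta.json"))
  expect_error(read_bundle(file.path(dir, "bad.tsv")), "ch002")
})

test_that("z-scoring normalises every channel and is idempotent", {
  rec <- make_rec()
  rec$signals <- sweep(rec$signals, 2L, c(1, 5, 0.2, 40), `*`) + 3
  z <- zscore_channels(rec)
  expect_true(all(abs(colMeans(z$signals)) < 1e-10))
  expect_true(all(abs(apply(z$signals, 2, stats::var) - 1) < 1e-8))
  z2 <- zscore_channels(z)
  expect_equal(z2$signals, z$signals, tolerance = 1e-10)
  rec$signals[, 3] <- 2
  expect_error(zscore_channels(rec), "ch003")
})

test_that("window grids follow the 500 ms tiling arithmetic", {
  # 3.0 s span between AD_Start and Qes_Start
  rec <- make_rec(n = 6000)
  tl <- timeline(c("AD_Start", "Qes_Start", "AD_End"), c(0.5, 3.5, 5.5),
                 rec = rec)
  g_no <- make_windows(rec, tl, "W1", "nonoverlap")
  expect_equal(nrow(g_no), 6L)                       # floor(3000 / 500)
  expect_true(all(g_no$end_sample - g_no$start_sample == 500L))
  g_ov <- make_windows(rec, tl, "W1", "overlap50")
  expect_equal(nrow(g_ov), 11L)                      # floor((3000-500)/250)+1
  expect_true(all(diff(g_ov$start_sample) == 250L))
})

test_that("intermediate markers restart the windowing", {
  # W2 spans 2.0 s with a marker 1.2 s in: 2 whole windows, then 1
  rec <- make_rec(n = 6000)
  tl <- timeline(c("AD_Start", "Qes_Start", "Qes_End", "AD_End"),
                 c(0.5, 1.5, 2.7, 3.5), rec = rec)
  g <- make_windows(rec, tl, "W2", "nonoverlap")
  expect_equal(nrow(g), 3L)
  expect_equal(g$start_sample, c(1500L, 2000L, 2700L))
  expect_equal(unique(g$span), c(1L, 2L))
  # no window straddles any marker
  marks <- round(tl$time_s * 1000)
  for (mk in marks) {
    expect_false(any(g$start_sample < mk & mk < g$end_sample))
  }
})

test_that("W1 and W2 tile the after-discharge interval exactly once", {
  rec <- make_rec()
  tl <- std_tl(rec)
  seg <- trial_segments(rec, tl)
  expect_equal(seg$w1[2], seg$w2[1])
  expect_equal(seg$w1[1], round(0.2 * 1000))
  expect_equal(seg$w2[2], round(3.7 * 1000))
})

test_that("spans shorter than one window give an empty grid with a warning", {
  rec <- make_rec()
  tl <- timeline(c("AD_Start", "Qes_Start", "AD_End"), c(0.2, 0.5, 3.7),
                 rec = rec)
  expect_warning(g <- make_windows(rec, tl, "W1", "nonoverlap"),
                 "shorter than one window")
  expect_equal(nrow(g), 0L)
})
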