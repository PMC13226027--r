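test_that("feature vectors are fixed-length and vanish for identical phases", {
  run <- small_run()
  tr <- run$trials[[1]]
  # identical W1/W2 dynamics: delta features are exactly zero
  tr_same <- tr
  tr_same$phases$W2 <- tr_same$phases$W1
  expect_equal(unname(extract_features(tr_same, "delta")), rep(0, 6))
  expect_length(extract_features(tr, "delta"), 6L)
  expect_length(extract_features(tr, "absolute_w2"), 6L)
  expect_length(extract_features(tr, "concat"), 12L)
  expect_length(extract_features(tr, "delta", include_width = TRUE), 7L)
  tr_miss <- tr; tr_miss$phases$W2 <- NULL
  expect_error(extract_features(tr_miss), "missing phase")
})

test_that("feature length does not depend on the channel count", {
  co <- gen_cohort(cohort_spec(n_trials = 2, n_success = 1, n_channels = 6,
                               w1_duration_s = c(3, 3.5),
                               w2_duration_s = c(4, 4.5), seed = 77))
  co2 <- gen_cohort(cohort_spec(n_trials = 2, n_success = 1, n_channels = 14,
                                w1_duration_s = c(3, 3.5),
                                w2_duration_s = c(4, 4.5), seed = 78))
  f1 <- extract_features(analyze_trial(co[[1]]$recording, co[[1]]$timeline))
  f2 <- extract_features(analyze_trial(co2[[1]]$recording, co2[[1]]$timeline))
  expect_identical(names(f1), names(f2))
})

test_that("success trials show the injected variability reduction", {
  run <- small_run()
  lab <- run$labels
  var_delta <- run$features[, "var_alpha"]
  expect_lt(max(var_delta[lab == "success"]), 0)
  expect_lt(mean(var_delta[lab == "success"]),
            mean(var_delta[lab == "failure"]))
})

test_that("LOOCV is perfect on separable features and chance on constants", {
  set.seed(12)
  n <- 43
  lab <- c(rep("success", 20), rep("failure", 23))
  feats <- cbind(f1 = ifelse(lab == "success", 2, -2) + rnorm(n, sd = 0.1),
                 f2 = rnorm(n))
  cv <- loocv_logistic(feats, lab)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(sum(cv$confusion), 43)

  const <- matrix(1, n, 3)
  cvc <- loocv_logistic(const, lab)
  expect_equal(cvc$auc, 0.5)
  expect_equal(cvc$accuracy, 23 / 43)     # majority rate
  expect_error(loocv_logistic(feats[1:3, ], lab[c(1, 2, 21)]),
               "at least 2 trials per class")
})

test_that("permuted labels carry no skill beyond the chance band", {
  set.seed(13)
  n <- 43
  lab <- c(rep("success", 20), rep("failure", 23))
  feats <- cbind(rnorm(n), rnorm(n), rnorm(n))
  accs <- replicate(200, loocv_logistic(feats, sample(lab))$accuracy)
  majority <- 23 / 43
  expect_lt(abs(mean(accs) - majority), 0.12)
})

test_that("fold standardisation never sees the held-out trial", {
  set.seed(14)
  n <- 20
  lab <- rep(c("success", "failure"), each = 10)
  feats <- matrix(rnorm(n * 4), n, 4)
  cv <- loocv_logistic(feats, lab)
  feats2 <- feats
  feats2[5, ] <- feats2[5, ] + 100      # perturb only the held-out trial
  cv2 <- loocv_logistic(feats2, lab)
  # the scaler of fold 5 (trained without trial 5) is unchanged ...
  expect_identical(cv$scalers[[5]], cv2$scalers[[5]])
  # ... while folds that train on trial 5 see a different scaler
  expect_false(identical(cv$scalers[[6]], cv2$scalers[[6]]))
})
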