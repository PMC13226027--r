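#' Fixed-length trial feature vector
#'
#' Reduces a trial's per-phase scaling and network tracks to the
#' descriptors used for outcome classification: the mean and variance
#' (across time windows and all channels) of the FODN fractional orders,
#' scalar summaries of the dominant eigenvector (mean maximum weight, mean
#' participation ratio, consecutive-window cosine stability -- the
#' permutation-stable reduction of a variable-length eigenvector to fixed
#' length), and the generalized Hurst summary (mean `h(2)`; the
#' multifractal width `h(-5) - h(5)` optionally). Phase handling:
#' `"delta"` (default) uses W2 minus W1 (the change induced by cognitive
#' effort), `"absolute_w2"` uses W2 alone, `"concat"` stacks both phases.
#' The feature length is fixed for a given mode regardless of channel
#' count.
#'
#' @param trial One analysed trial (element of [run_pipeline()]`$trials`),
#'   holding `scaling` and `fodn` tracks for both phases.
#' @param mode `"delta"`, `"absolute_w2"` or `"concat"`.
#' @param include_width Also include the multifractal width (default
#'   FALSE).
#' @return Named numeric feature vector.
#' @export
extract_features <- function(trial, mode = c("delta", "absolute_w2", "concat"),
                             include_width = FALSE) {
  mode <- match.arg(mode)
  phase_feats <- function(ph) {
    if (is.null(ph)) stop("missing phase in trial analysis", call. = FALSE)
    fodn <- ph$fodn
    sc <- ph$scaling
    al <- fodn$alpha_track[is.finite(fodn$alpha_track)]
    f <- c(mean_alpha = mean(al),
           var_alpha = stats::var(al),
           eig_max = mean(fodn$max_weight, na.rm = TRUE),
           eig_pr = mean(fodn$participation, na.rm = TRUE),
           eig_stab = fodn$cos_stability,
           gen_hurst = mean(sc$gH, na.rm = TRUE))
    if (include_width) {
      q <- as.numeric(rownames(sc$hq))
      wdt <- mean(sc$hq[match(-5, q), , ] - sc$hq[match(5, q), , ], na.rm = TRUE)
      f <- c(f, mf_width = wdt)
    }
    f
  }
  f1 <- phase_feats(trial$phases$W1)
  f2 <- phase_feats(trial$phases$W2)
  switch(mode,
         delta = f2 - f1,
         absolute_w2 = f2,
         concat = c(stats::setNames(f1, paste0("w1_", names(f1))),
                    stats::setNames(f2, paste0("w2_", names(f2)))))
}

#' Leave-one-trial-out logistic-regression evaluation
#'
#' Each trial is held out once; the model is trained on the rest and
#' predicts the held-out trial at a 0.5 probability threshold. Features are
#' standardized with training-fold statistics only (strictly no use of the
#' held-out trial, avoiding the leakage a global normalization would
#' introduce), and the model is an L2-penalised logistic regression with a
#' fixed regularization strength (no nested tuning; the trial counts here
#' cannot support it). The ROC curve and AUC are computed from the pooled
#' out-of-fold probabilities.
#'
#' @param features Trials x features numeric matrix (rownames = trial ids).
#' @param labels Outcome per trial, `"success"`/`"failure"` (>= 2 of each).
#' @param seed Optional seed (the fit itself is deterministic; the seed
#'   covers any downstream resampling a caller wires in).
#' @param lambda Fixed L2 penalty passed to the ridge-logistic fit.
#' @param threshold Decision threshold on the success probability.
#' @return Object of class `cv_report`: list with `folds` (per-fold truth,
#'   probability, prediction, flag), `confusion` (2x2, success = positive),
#'   `accuracy`, `precision`, `recall` (per class), `roc`
#'   (data.frame of ROC points), `auc`, and `scalers` (the per-fold
#'   training standardization statistics, exposed so leakage-freedom is
#'   testable).
#' @export
loocv_logistic <- function(features, labels, seed = NULL, lambda = 0.05,
                           threshold = 0.5) {
  features <- as.matrix(features)
  n <- nrow(features)
  labels <- factor(as.character(labels), levels = c("failure", "success"))
  if (length(labels) != n) stop("one label per trial required", call. = FALSE)
  if (any(table(labels) < 2L)) {
    stop("need at least 2 trials per class", call. = FALSE)
  }
  prob <- rep(NA_real_, n)
  flagged <- logical(n)
  force_pred <- rep(NA_character_, n)
  scalers <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      tr_x <- features[-i, , drop = FALSE]
      tr_y <- labels[-i]
      mu <- colMeans(tr_x)
      sdv <- apply(tr_x, 2L, stats::sd)
      if (all(sdv == 0 | !is.finite(sdv))) {
        # no usable feature variation: the fold is uninformative; predict
        # the training majority at a neutral probability
        flagged[i] <- TRUE
        scalers[[i]] <- list(center = mu, scale = rep(1, length(mu)))
        prob[i] <- 0.5
        force_pred[i] <- names(which.max(table(tr_y)))
        next
      }
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      scalers[[i]] <- list(center = mu, scale = sdv)
      xs <- sweep(sweep(tr_x, 2L, mu), 2L, sdv, `/`)
      xt <- (features[i, ] - mu) / sdv
      if (nlevels(droplevels(tr_y)) < 2L) {
        flagged[i] <- TRUE
        prob[i] <- mean(tr_y == "success")
        next
      }
      fit <- tryCatch(
        suppressWarnings(glmnet::glmnet(xs, tr_y, family = "binomial", alpha = 0,
                       lambda = sort(unique(c(5, 1, 0.2, lambda)),
                                     decreasing = TRUE),
                       standardize = FALSE)),
        error = function(e) NULL)
      if (is.null(fit)) {
        flagged[i] <- TRUE
        prob[i] <- mean(tr_y == "success")
        next
      }
      prob[i] <- as.numeric(stats::predict(fit, matrix(xt, nrow = 1L),
                                           s = lambda, type = "response"))
    }
  })
  pred <- factor(ifelse(is.na(force_pred),
                        ifelse(prob >= threshold, "success", "failure"),
                        force_pred),
                 levels = c("failure", "success"))
  tp <- sum(pred == "success" & labels == "success")
  fp <- sum(pred == "success" & labels == "failure")
  tn <- sum(pred == "failure" & labels == "failure")
  fn <- sum(pred == "failure" & labels == "success")
  confusion <- matrix(c(tn, fn, fp, tp), 2L, 2L,
                      dimnames = list(predicted = c("failure", "success"),
                                      truth = c("failure", "success")))
  prec <- c(failure = tn / max(tn + fn, 1L), success = tp / max(tp + fp, 1L))
  rec <- c(failure = tn / max(tn + fp, 1L), success = tp / max(tp + fn, 1L))
  roc_obj <- tryCatch(
    pROC::roc(response = labels, predictor = prob,
              levels = c("failure", "success"), direction = "<",
              quiet = TRUE),
    error = function(e) NULL)
  if (is.null(roc_obj) || length(unique(prob)) == 1L) {
    auc <- 0.5
    roc_df <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
  } else {
    auc <- as.numeric(pROC::auc(roc_obj))
    roc_df <- data.frame(fpr = 1 - roc_obj$specificities,
                         tpr = roc_obj$sensitivities)
    roc_df <- roc_df[order(roc_df$fpr, roc_df$tpr), ]
  }
  folds <- data.frame(trial = rownames(features) %||% as.character(seq_len(n)),
                      truth = labels, prob = prob, pred = pred,
                      flagged = flagged)
  structure(list(folds = folds, confusion = confusion,
                 accuracy = (tp + tn) / n, precision = prec, recall = rec,
                 roc = roc_df, auc = auc, lambda = lambda,
                 threshold = threshold, scalers = scalers),
            class = "cv_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
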