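#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis so that a run is fully
#' described (and reproducible) by its config plus seed.
#'
#' @param window_mode `"nonoverlap"` or `"overlap50"`.
#' @param scaling A [scaling_config()].
#' @param fodn_lambda_ridge,fodn_lambda_lasso,fodn_iters,fodn_J,fodn_alpha_levels
#'   FODN fitting controls (see [fit_fodn()]); `NULL` penalties use the
#'   data-scaled defaults.
#' @param feature_mode Feature phase handling (see [extract_features()]).
#' @param cv_lambda Fixed L2 strength of the LOOCV logistic regression.
#' @param seed Root seed for the run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_mode = c("nonoverlap", "overlap50"),
                            scaling = scaling_config(),
                            fodn_lambda_ridge = NULL, fodn_lambda_lasso = NULL,
                            fodn_iters = 3L, fodn_J = 50L,
                            fodn_alpha_levels = 4L,
                            feature_mode = "delta", cv_lambda = 0.05,
                            seed = NULL) {
  structure(list(window_mode = match.arg(window_mode), scaling = scaling,
                 fodn_lambda_ridge = fodn_lambda_ridge,
                 fodn_lambda_lasso = fodn_lambda_lasso,
                 fodn_iters = fodn_iters, fodn_J = fodn_J,
                 fodn_alpha_levels = fodn_alpha_levels,
                 feature_mode = feature_mode, cv_lambda = cv_lambda,
                 seed = seed),
            class = "pipeline_config")
}

#' Analyse one trial: windows, scaling tracks, network tracks
#'
#' Z-scores the recording, lays the W1/W2 window grids, and runs the
#' windowed scaling scan and FODN identification on both phases.
#'
#' @param rec An `ad_recording`.
#' @param tl An `ad_timeline`.
#' @param config A [pipeline_config()].
#' @return List with `trial_id`, `outcome`, and `phases$W1`/`phases$W2`,
#'   each holding the `grid`, `scaling` (`scaling_tracks`) and `fodn`
#'   (`fodn_track`) results.
#' @export
analyze_trial <- function(rec, tl, config = pipeline_config()) {
  rec <- zscore_channels(rec)
  phases <- lapply(c(W1 = "W1", W2 = "W2"), function(seg) {
    grid <- make_windows(rec, tl, segment = seg, mode = config$window_mode)
    list(grid = grid,
         scaling = windowed_scan(rec, grid, config$scaling),
         fodn = windowed_fodn(rec, grid,
                              lambda_ridge = config$fodn_lambda_ridge,
                              lambda_lasso = config$fodn_lambda_lasso,
                              n_alt_iters = config$fodn_iters,
                              J = config$fodn_J,
                              alpha_levels = config$fodn_alpha_levels))
  })
  list(trial_id = rec$trial_id, outcome = rec$outcome, phases = phases)
}

#' Run the full pipeline on a cohort
#'
#' Executes the stage sequence validate -> windows -> scaling -> FODN ->
#' group statistics -> features -> leave-one-trial-out classification on a
#' cohort (either a list from [gen_cohort()] or a directory of bundles
#' written by [write_bundle()]). Identical input, config and seed give
#' identical output.
#'
#' @param cohort List of `list(recording, timeline)` trials, or a directory
#'   path containing `.tsv` + `.meta.json` bundles.
#' @param config A [pipeline_config()].
#' @param progress Print one line per trial.
#' @return Object of class `ad_run`: list with `trials` (per-trial
#'   analyses), `features` (trials x features matrix), `labels`, `cv`
#'   (`cv_report`), `pooled_ks` (per outcome class, W1 vs W2 KS on the
#'   pooled per-channel Hurst means), `pool_sizes`, and `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), progress = FALSE) {
  if (is.character(cohort)) {
    paths <- sort(list.files(cohort, pattern = "\\.tsv$", full.names = TRUE))
    if (!length(paths)) stop("no .tsv bundles in ", cohort, call. = FALSE)
    cohort <- lapply(paths, function(p) {
      tryCatch(read_bundle(p),
               error = function(e) stop("invalid bundle '", basename(p), "': ",
                                        conditionMessage(e), call. = FALSE))
    })
  }
  trials <- lapply(seq_along(cohort), function(i) {
    tr <- cohort[[i]]
    if (progress) message("trial ", i, "/", length(cohort), " (", tr$recording$trial_id, ")")
    tryCatch(analyze_trial(tr$recording, tr$timeline, config),
             error = function(e) stop("stage 'analyze' failed for trial '",
                                      tr$recording$trial_id, "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  labels <- vapply(trials, `[[`, character(1), "outcome")
  feats <- t(vapply(trials, extract_features, mode = config$feature_mode,
                    FUN.VALUE = extract_features(trials[[1L]],
                                                 mode = config$feature_mode)))
  rownames(feats) <- vapply(trials, `[[`, character(1), "trial_id")
  pooled_ks <- list(); pool_sizes <- list()
  for (oc in intersect(c("success", "failure"), unique(labels))) {
    if (sum(labels == oc) < 1L) next
    p1 <- pool_exponents(trials, "W1", oc)
    p2 <- pool_exponents(trials, "W2", oc)
    pooled_ks[[oc]] <- ks_two_sample(p1$value, p2$value)
    pool_sizes[[oc]] <- c(W1 = nrow(p1), W2 = nrow(p2))
  }
  cv <- NULL
  if (all(table(factor(labels, levels = c("failure", "success"))) >= 2L)) {
    cv <- loocv_logistic(feats, labels, seed = config$seed,
                         lambda = config$cv_lambda)
  }
  structure(list(trials = trials, features = feats, labels = labels, cv = cv,
                 pooled_ks = pooled_ks, pool_sizes = pool_sizes,
                 config = config),
            class = "ad_run")
}
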