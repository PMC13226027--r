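#' Construct a trial recording
#'
#' Container for one multichannel trial: a samples x channels numeric matrix
#' plus its acquisition metadata. Values are in z-score units after
#' [zscore_channels()]; raw generator output is accepted too.
#'
#' @param signals Numeric matrix, samples x channels.
#' @param fs_hz Sampling rate in Hz (> 0); recordings here are 1000 Hz.
#' @param channel_labels Unique channel names (default `ch001 ...`).
#' @param patient_id,trial_id Identifiers.
#' @param outcome One of `"success"`, `"failure"`, `"unknown"`.
#' @return Object of class `ad_recording`.
#' @export
recording <- function(signals, fs_hz, channel_labels = NULL,
                      patient_id = "p01", trial_id = "t01",
                      outcome = c("unknown", "success", "failure")) {
  signals <- as.matrix(signals)
  outcome <- match.arg(outcome)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0) {
    stop("`fs_hz` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%03d", seq_len(ncol(signals)))
  }
  if (length(channel_labels) != ncol(signals)) {
    stop("channel label count must equal signal column count", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (any(!is.finite(signals))) {
    bad <- which(colSums(!is.finite(signals)) > 0)
    stop("non-finite samples in channel(s): ",
         paste(channel_labels[bad], collapse = ", "), call. = FALSE)
  }
  colnames(signals) <- channel_labels
  structure(list(signals = signals, fs_hz = fs_hz,
                 channel_labels = channel_labels, patient_id = patient_id,
                 trial_id = trial_id, outcome = outcome),
            class = "ad_recording")
}

.MANDATORY_MARKERS <- c("AD_Start", "Qes_Start", "AD_End")
.KNOWN_MARKERS <- c("AD_Start", "Qes_Start", "Qes_End",
                    "Ans_Start", "Ans_End", "AD_End")

#' Construct and validate an event timeline
#'
#' Ordered trial event markers in seconds. `AD_Start`, `Qes_Start` and
#' `AD_End` are mandatory; `Qes_End`, `Ans_Start`, `Ans_End` are optional
#' intermediate markers (analysis windows restart at every marker). Times
#' must be strictly increasing and, when `rec` is given, lie within the
#' recording span.
#'
#' @param name Character vector of marker names.
#' @param time_s Numeric vector of marker times (seconds).
#' @param rec Optional `ad_recording` to validate the span against.
#' @return Object of class `ad_timeline` (data.frame with `name`, `time_s`).
#' @export
timeline <- function(name, time_s, rec = NULL) {
  if (length(name) != length(time_s)) {
    stop("`name` and `time_s` must have equal length", call. = FALSE)
  }
  unknown <- setdiff(name, .KNOWN_MARKERS)
  if (length(unknown)) {
    stop("unknown marker(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(.MANDATORY_MARKERS, name)
  if (length(missing)) {
    stop("missing mandatory marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(name)) stop("duplicated marker names", call. = FALSE)
  ord <- order(time_s)
  df <- data.frame(name = name[ord], time_s = time_s[ord],
                   stringsAsFactors = FALSE)
  if (any(diff(df$time_s) <= 0)) {
    i <- which(diff(df$time_s) <= 0)[1L]
    stop(sprintf("marker times not strictly increasing at '%s' (%.4f s)",
                 df$name[i + 1L], df$time_s[i + 1L]), call. = FALSE)
  }
  # mandatory markers must keep their canonical order
  pos <- match(.MANDATORY_MARKERS, df$name)
  if (any(diff(pos) <= 0)) {
    bad <- .MANDATORY_MARKERS[which(diff(pos) <= 0)[1L] + 1L]
    stop(sprintf("marker '%s' out of order", bad), call. = FALSE)
  }
  if (!is.null(rec)) {
    span <- nrow(rec$signals) / rec$fs_hz
    if (df$time_s[1L] < 0 || df$time_s[nrow(df)] > span) {
      stop(sprintf("marker '%s' outside the recording span [0, %.3f] s",
                   df$name[if (df$time_s[1L] < 0) 1L else nrow(df)], span),
           call. = FALSE)
    }
  }
  structure(df, class = c("ad_timeline", "data.frame"))
}

#' Write a trial bundle to disk
#'
#' One trial is stored as `<trial_id>.tsv` (tab-separated, header row of
#' channel labels, samples x channels, full double precision) plus
#' `<trial_id>.meta.json` carrying `fs_hz`, identifiers, outcome, the event
#' timeline, and an optional `excluded_channels` list.
#'
#' @param rec An `ad_recording`.
#' @param tl An `ad_timeline`.
#' @param dir Output directory (created if needed).
#' @param excluded_channels Channel labels to be dropped on read.
#' @return Invisibly, the two file paths.
#' @export
write_bundle <- function(rec, tl, dir, excluded_channels = character()) {
  stopifnot(inherits(rec, "ad_recording"), inherits(tl, "ad_timeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_path <- file.path(dir, paste0(rec$trial_id, ".tsv"))
  meta_path <- file.path(dir, paste0(rec$trial_id, ".meta.json"))
  df <- as.data.frame(rec$signals)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     sig_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(fs_hz = rec$fs_hz, patient_id = rec$patient_id,
               trial_id = rec$trial_id, outcome = rec$outcome,
               n_samples = nrow(rec$signals), n_channels = ncol(rec$signals),
               orientation = "samples_x_channels",
               events = data.frame(name = tl$name, time_s = tl$time_s),
               excluded_channels = I(excluded_channels))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(signals = sig_path, meta = meta_path))
}

#' Read and validate a trial bundle
#'
#' Reads a `<trial>.tsv` + `<trial>.meta.json` pair, validates the event
#' timeline (mandatory markers, strict ordering, span) and the signal matrix
#' (no NaN/Inf, labels match columns), and drops the channels listed in
#' `excluded_channels` (artifact-dominated electrodes identified upstream).
#'
#' @param signals_path Path to the `.tsv` signal table.
#' @param meta_path Path to the metadata JSON; defaults to the signal path
#'   with `.tsv` replaced by `.meta.json`.
#' @return List with `recording` (`ad_recording`) and `timeline`
#'   (`ad_timeline`).
#' @export
read_bundle <- function(signals_path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.tsv$", ".meta.json", signals_path)
  if (!file.exists(signals_path)) stop("missing signal file: ", signals_path, call. = FALSE)
  if (!file.exists(meta_path)) stop("missing metadata file: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  sig <- utils::read.table(signals_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "numeric")
  sig <- as.matrix(sig)
  if (any(is.na(sig)) || any(!is.finite(sig))) {
    bad <- which(colSums(!is.finite(sig)) > 0)
    stop("NaN/Inf cells in channel(s): ",
         paste(colnames(sig)[bad], collapse = ", "), call. = FALSE)
  }
  excl <- unlist(meta$excluded_channels)
  if (length(excl)) {
    keep <- !(colnames(sig) %in% excl)
    sig <- sig[, keep, drop = FALSE]
  }
  rec <- recording(sig, fs_hz = meta$fs_hz, channel_labels = colnames(sig),
                   patient_id = meta$patient_id, trial_id = meta$trial_id,
                   outcome = if (is.null(meta$outcome)) "unknown" else meta$outcome)
  tl <- timeline(meta$events$name, meta$events$time_s, rec = rec)
  list(recording = rec, timeline = tl)
}

#' Z-score every channel over time
#'
#' Subtracts the per-channel mean and divides by the per-channel standard
#' deviation (whole-trial statistics; idempotent up to float precision).
#'
#' @param rec An `ad_recording`.
#' @return The recording with columnwise mean 0 and variance 1.
#' @export
zscore_channels <- function(rec) {
  stopifnot(inherits(rec, "ad_recording"))
  sds <- apply(rec$signals, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- which(sds == 0 | !is.finite(sds))
    stop("zero-variance channel(s): ",
         paste(rec$channel_labels[bad], collapse = ", "), call. = FALSE)
  }
  rec$signals <- scale(rec$signals)
  attr(rec$signals, "scaled:center") <- NULL
  attr(rec$signals, "scaled:scale") <- NULL
  rec
}

#' Phase boundaries of a trial in sample coordinates
#'
#' W1 runs from after-discharge onset to question onset, W2 from question
#' onset to after-discharge end; together they tile `[AD_Start, AD_End)`
#' exactly once. Intervals are 0-based half-open sample indices; marker
#' times are converted by rounding to the nearest sample.
#'
#' @param rec An `ad_recording`.
#' @param tl An `ad_timeline`.
#' @return List with `w1` and `w2`, each `c(start, end)` (half-open).
#' @export
trial_segments <- function(rec, tl) {
  tt <- function(nm) round(tl$time_s[match(nm, tl$name)] * rec$fs_hz)
  w1 <- c(tt("AD_Start"), tt("Qes_Start"))
  w2 <- c(tt("Qes_Start"), tt("AD_End"))
  if (w1[2L] <= w1[1L] || w2[2L] <= w2[1L]) {
    stop("empty trial segment", call. = FALSE)
  }
  list(w1 = w1, w2 = w2)
}

#' Lay the 500 ms analysis window grid over a trial phase
#'
#' Windows of `window_s` seconds are laid within each inter-marker span of
#' the requested phase, starting at the span start, stepping one window
#' length (`nonoverlap`) or half a window length (`overlap50`). Windows
#' never cross an event marker: every marker inside the phase restarts the
#' grid (mirroring behavioural markers such as `Qes_End` that interrupt the
#' windowing). Trailing partial windows are dropped.
#'
#' @param rec An `ad_recording`.
#' @param tl An `ad_timeline`.
#' @param segment `"W1"` or `"W2"`.
#' @param mode `"nonoverlap"` or `"overlap50"`.
#' @param window_s Window length in seconds (default 0.5).
#' @return Object of class `ad_windows`: data.frame with 0-based half-open
#'   `start_sample`, `end_sample` and the originating `span` index; may have
#'   zero rows (with a warning) if every span is shorter than one window.
#' @export
make_windows <- function(rec, tl, segment = c("W1", "W2"),
                         mode = c("nonoverlap", "overlap50"), window_s = 0.5) {
  segment <- match.arg(segment)
  mode <- match.arg(mode)
  seg <- trial_segments(rec, tl)[[if (segment == "W1") "w1" else "w2"]]
  marks <- round(tl$time_s * rec$fs_hz)
  inner <- sort(unique(marks[marks > seg[1L] & marks < seg[2L]]))
  bounds <- c(seg[1L], inner, seg[2L])
  wlen <- round(window_s * rec$fs_hz)
  step <- if (mode == "nonoverlap") wlen else round(window_s * rec$fs_hz / 2)
  out <- list()
  for (sp in seq_len(length(bounds) - 1L)) {
    a <- bounds[sp]; b <- bounds[sp + 1L]
    if (b - a < wlen) next
    starts <- seq(a, b - wlen, by = step)
    out[[length(out) + 1L]] <- data.frame(start_sample = starts,
                                          end_sample = starts + wlen,
                                          span = sp)
  }
  if (!length(out)) {
    warning("every span of ", segment, " is shorter than one window",
            call. = FALSE)
    grid <- data.frame(start_sample = integer(), end_sample = integer(),
                       span = integer())
  } else {
    grid <- do.call(rbind, out)
  }
  structure(grid, class = c("ad_windows", "data.frame"),
            mode = mode, window_s = window_s, segment = segment)
}
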