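# Preprocessing and denoising: zero-phase band-pass filtering, subject
# screening from the behavioural log, the accelerometer + amplitude artifact
# screen, and extraction of fixed-length epochs from the clean middle of each
# logged interval.

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth applied forward and backward (`signal::filtfilt`), so
#' the net phase response is zero and the output has the input's length.
#'
#' @param x numeric vector or samples-x-channels matrix.
#' @param rate sampling rate, samples/s.
#' @param low,high band edges in Hz; `0 < low < high < rate/2`.
#' @param order Butterworth order before the forward-backward doubling.
#' @return filtered vector/matrix of the same shape.
#' @export
bandpass_filter <- function(x, rate, low = 1, high = 50, order = 4) {
  if (!(low > 0 && low < high && high < rate / 2)) {
    validation_error("band edges must satisfy 0 < low < high < rate/2")
  }
  mat <- is.matrix(x)
  xm <- if (mat) x else matrix(x, ncol = 1)
  warmup <- 3 * (2 * order + 1)
  if (nrow(xm) <= warmup) {
    validation_error(sprintf("signal too short for filtering (%d samples <= %d warm-up)",
                             nrow(xm), warmup))
  }
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  # odd-reflection padding confines the filter's edge transients to the pads
  # (the slow pole sits at the low edge, hence the 3 / low time constant);
  # averaging with the time-reversed application makes the operator exactly
  # symmetric under reversal
  pad <- min(nrow(xm) - 1L, as.integer(ceiling(3 * rate / low)))
  core <- function(col) {
    n <- length(col)
    ext <- c(2 * col[1] - col[(pad + 1):2], col, 2 * col[n] - col[(n - 1):(n - pad)])
    signal::filtfilt(bf, ext)[(pad + 1):(pad + n)]
  }
  out <- apply(xm, 2, function(col) (core(col) + rev(core(rev(col)))) / 2)
  if (mat) {
    dimnames(out) <- dimnames(x)
    out
  } else {
    as.numeric(out)
  }
}

#' Screen subjects by behavioural log flags
#'
#' A subject is excluded if and only if any of their log entries carries one
#' of the flags: logging inconsistencies, gum chewing, excessive head motion,
#' or talking to other participants.
#'
#' @param log an [event_log()].
#' @return data.frame with columns `subject` and `reasons` (`;`-separated,
#'   deduplicated); zero rows when no subject is flagged.
#' @export
screen_subjects <- function(log) {
  flagged <- log[log$flags != "", , drop = FALSE]
  if (nrow(flagged) == 0L) {
    return(data.frame(subject = character(0), reasons = character(0),
                      stringsAsFactors = FALSE))
  }
  by_subj <- split(flagged$flags, flagged$subject)
  reasons <- vapply(by_subj, function(f) {
    paste(sort(unique(unlist(strsplit(f, ";")))), collapse = ";")
  }, character(1))
  data.frame(subject = names(reasons), reasons = unname(reasons),
             stringsAsFactors = FALSE)
}

#' Multimodal artifact detection
#'
#' An EEG sample is flagged artifactual if (a) the time-aligned accelerometer
#' sample (nearest preceding sample at the accelerometer rate) exceeds
#' `accel_thresh` in absolute value -- on all three axes under the default
#' `axis_rule = "all"`, on any axis under `"any"` -- or (b) the band-passed
#' amplitude of any EEG channel exceeds `amp_thresh` in absolute value.
#' Flags are dilated by `dilate_s` seconds on each side so epochs avoid
#' artifact shoulders.
#'
#' @param rec a `recording` (must include the accelerometer stream).
#' @param accel_thresh accelerometer threshold, m/s^2.
#' @param amp_thresh EEG amplitude threshold, uV (applied to the 1-50 Hz
#'   filtered signal).
#' @param axis_rule `"all"` (conjunctive, literal reading) or `"any"`.
#' @param dilate_s dilation margin in seconds on each side of a flagged run.
#' @param low,high band edges for the amplitude criterion's filter.
#' @param filtered optional pre-filtered EEG matrix to avoid re-filtering.
#' @return object of class `artifact_mask`: list with `mask` (logical per EEG
#'   sample, TRUE = artifactual), pre-dilation criterion vectors
#'   `acceleration` and `amplitude`, and `runs` (flagged runs with provenance).
#' @export
detect_artifacts <- function(rec, accel_thresh = 2, amp_thresh = 40,
                             axis_rule = c("all", "any"), dilate_s = 0.5,
                             low = 1, high = 50, filtered = NULL) {
  stopifnot(inherits(rec, "recording"))
  axis_rule <- match.arg(axis_rule)
  if (nrow(rec$accel) == 0L) {
    validation_error("accelerometer stream required for artifact detection")
  }
  n <- nrow(rec$eeg)
  if (n == 0L) {
    return(structure(list(mask = logical(0), acceleration = logical(0),
                          amplitude = logical(0),
                          runs = data.frame(start = integer(0), end = integer(0),
                                            reason = character(0))),
                     class = "artifact_mask"))
  }
  # zero-order-hold alignment: nearest preceding accelerometer sample
  ai <- findInterval(rec$eeg_times, rec$accel_times)
  ai[ai < 1L] <- 1L
  absa <- abs(rec$accel)
  hit <- absa > accel_thresh
  accel_flag_acc <- if (axis_rule == "all") {
    hit[, 1] & hit[, 2] & hit[, 3]
  } else {
    hit[, 1] | hit[, 2] | hit[, 3]
  }
  acceleration <- accel_flag_acc[ai]

  if (is.null(filtered)) filtered <- bandpass_filter(rec$eeg, rec$eeg_rate, low, high)
  amplitude <- apply(abs(filtered) > amp_thresh, 1, any)

  raw <- acceleration | amplitude
  margin <- as.integer(round(dilate_s * rec$eeg_rate))
  mask <- dilate_flags(raw, margin)

  runs <- true_runs(mask)
  runs$reason <- vapply(seq_len(nrow(runs)), function(i) {
    span <- runs$start[i]:runs$end[i]
    paste(c(if (any(acceleration[span])) "acceleration",
            if (any(amplitude[span])) "amplitude"), collapse = ";")
  }, character(1))
  structure(list(mask = mask, acceleration = acceleration, amplitude = amplitude,
                 runs = runs),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("Artifact mask: %d/%d samples flagged in %d runs\n",
              sum(x$mask), length(x$mask), nrow(x$runs)))
  invisible(x)
}

# Center-tiled window starts inside a run of `len` samples.
tile_centered <- function(len, window, step) {
  if (len < window) return(integer(0))
  k <- (len - window) %/% step + 1L
  span <- window + (k - 1L) * step
  offset <- (len - span) %/% 2L
  offset + seq(0L, by = step, length.out = k) + 1L
}

#' Extract fixed-length epochs from the clean middle of logged intervals
#'
#' Within each logged interval, the longest artifact-free run is tiled with
#' windows centered on the run's midpoint (default: non-overlapping 256
#' sample windows, about 1.16 s at 220 samples/s). Each window yields one
#' epoch per EEG channel, labeled with subject, sensor, condition and any
#' questionnaire attributes supplied.
#'
#' @param rec a `recording`.
#' @param mask an `artifact_mask` for `rec` (or NULL to treat all samples as
#'   clean).
#' @param log an [event_log()] (entries for other subjects are ignored).
#' @param window epoch length in samples.
#' @param overlap fraction of window overlap between consecutive epochs in
#'   `[0, 1)`; 0 means non-overlapping tiling.
#' @param subject_info optional one-row data.frame (or list) with fields such
#'   as `gender`, `explained`, `favorite_piece` copied onto every epoch.
#' @param data EEG matrix to slice (defaults to the band-passed recording is
#'   NOT applied here; pass the filtered matrix for spectral work).
#' @return object of class `epoch_set`: list with `data` (n_epochs x window
#'   matrix), `labels` (data.frame: subject, sensor, condition, start_s, plus
#'   subject_info fields), `window`, `rate`, `duration_s`.
#' @export
extract_epochs <- function(rec, mask, log, window = 256L, overlap = 0,
                           subject_info = NULL, data = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (overlap < 0 || overlap >= 1) validation_error("'overlap' must be in [0, 1)")
  window <- as.integer(window)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  clean <- if (is.null(mask)) rep(TRUE, nrow(rec$eeg)) else !mask$mask
  if (is.null(data)) data <- rec$eeg
  entries <- log[log$subject == rec$subject, , drop = FALSE]
  epochs <- list()
  labels <- list()
  for (i in seq_len(nrow(entries))) {
    idx <- which(rec$eeg_times >= entries$start_s[i] - 1e-12 &
                   rec$eeg_times < entries$end_s[i] - 1e-12)
    if (length(idx) < window) next
    runs <- true_runs(clean[idx])
    if (nrow(runs) == 0L) next
    lens <- runs$end - runs$start + 1L
    best <- which.max(lens) # ties: first (earliest) run
    if (lens[best] < window) next
    run_idx <- idx[runs$start[best]:runs$end[best]]
    starts <- tile_centered(lens[best], window, step)
    for (s0 in starts) {
      sel <- run_idx[s0:(s0 + window - 1L)]
      for (ch in CHANNELS) {
        epochs[[length(epochs) + 1L]] <- data[sel, ch]
        labels[[length(labels) + 1L]] <- data.frame(
          subject = rec$subject, sensor = ch, condition = entries$condition[i],
          start_s = rec$eeg_times[sel[1]], stringsAsFactors = FALSE)
      }
    }
  }
  lab <- if (length(labels)) do.call(rbind, labels) else
    data.frame(subject = character(0), sensor = character(0),
               condition = character(0), start_s = numeric(0))
  if (!is.null(subject_info)) {
    info <- as.data.frame(as.list(subject_info), stringsAsFactors = FALSE)
    info <- info[setdiff(names(info), names(lab))]
    if (nrow(lab) > 0 && ncol(info) > 0) {
      lab <- cbind(lab, info[rep(1L, nrow(lab)), , drop = FALSE])
      rownames(lab) <- NULL
    }
  }
  dat <- if (length(epochs)) do.call(rbind, epochs) else
    matrix(numeric(0), 0, window)
  structure(list(data = dat, labels = lab, window = window, rate = rec$eeg_rate,
                 duration_s = window / rec$eeg_rate),
            class = "epoch_set")
}

#' Combine epoch sets from several subjects
#' @param ... `epoch_set` objects (or a single list of them).
#' @return a combined `epoch_set`.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "epoch_set")) sets <- sets[[1]]
  sets <- Filter(function(s) nrow(s$data) > 0, sets)
  if (!length(sets)) validation_error("no non-empty epoch sets to combine")
  stopifnot(length(unique(vapply(sets, `[[`, 1, "window"))) == 1L)
  labs <- lapply(sets, `[[`, "labels")
  common <- Reduce(intersect, lapply(labs, names))
  structure(list(
    data = do.call(rbind, lapply(sets, `[[`, "data")),
    labels = do.call(rbind, lapply(labs, function(l) l[, common, drop = FALSE])),
    window = sets[[1]]$window, rate = sets[[1]]$rate,
    duration_s = sets[[1]]$duration_s), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d epochs x %d samples (%.2f s at %g Hz)\n",
              nrow(x$data), x$window, x$duration_s, x$rate))
  if (nrow(x$labels)) {
    tab <- table(x$labels$condition)
    cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}
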