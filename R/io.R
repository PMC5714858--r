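# On-disk dialects: plain CSV with one header line, times in seconds.
# One EEG file and one accelerometer file per subject, a shared events table,
# a questionnaire table, and a YAML manifest tying a study together.

#' Construct a validated recording
#'
#' @param subject subject identifier.
#' @param eeg numeric matrix, samples x 4 channels in uV; columns must be
#'   TP9, AF7, AF8, TP10 in that order.
#' @param eeg_times,accel_times strictly increasing times in seconds.
#' @param accel numeric matrix, samples x 3 axes in m/s^2.
#' @param eeg_rate,accel_rate nominal sampling rates (samples/s).
#' @return object of class `recording`.
#' @export
recording <- function(subject, eeg, eeg_times, accel, accel_times,
                      eeg_rate = 220, accel_rate = 50) {
  eeg <- as.matrix(eeg)
  accel <- as.matrix(accel)
  if (ncol(eeg) != 4L) {
    validation_error(sprintf("EEG must have exactly 4 channels, got %d", ncol(eeg)))
  }
  colnames(eeg) <- CHANNELS
  colnames(accel) <- c("ax", "ay", "az")
  if (ncol(accel) != 3L) validation_error("accelerometer must have 3 axes")
  if (nrow(eeg) != length(eeg_times)) validation_error("EEG times/samples length mismatch")
  if (nrow(accel) != length(accel_times)) validation_error("accel times/samples length mismatch")
  check_monotone <- function(tm, what) {
    if (length(tm) > 1L && any(diff(tm) <= 0)) {
      bad <- which(diff(tm) <= 0)[1] + 1L
      parse_error(sprintf("%s timestamps not strictly increasing at sample %d", what, bad))
    }
  }
  check_monotone(eeg_times, "EEG")
  check_monotone(accel_times, "accelerometer")
  check_rate <- function(tm, rate, what) {
    if (length(tm) > 1L) {
      obs <- (length(tm) - 1) / (tm[length(tm)] - tm[1])
      if (abs(obs - rate) / rate > 0.01) {
        validation_error(sprintf("%s rate %.3f drifts more than 1%% from nominal %g", what, obs, rate))
      }
    }
  }
  check_rate(eeg_times, eeg_rate, "EEG")
  check_rate(accel_times, accel_rate, "accelerometer")
  structure(list(subject = as.character(subject), eeg = eeg, eeg_times = as.numeric(eeg_times),
                 accel = accel, accel_times = as.numeric(accel_times),
                 eeg_rate = eeg_rate, accel_rate = accel_rate),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording %s: %d EEG samples @ %g Hz (%s), %d accel samples @ %g Hz\n",
              x$subject, nrow(x$eeg), x$eeg_rate, paste(CHANNELS, collapse = ","),
              nrow(x$accel), x$accel_rate))
  invisible(x)
}

#' Construct/validate an event log
#'
#' An event log assigns, per subject, non-overlapping time intervals to
#' conditions (`BL` or `P1`-`P8`) and may carry behavioural flags
#' (`talking`, `gum`, `excessive_motion`, `log_inconsistent`) separated by
#' `;` in the `flags` column.
#'
#' @param df data.frame with columns subject, group, condition, start_s,
#'   end_s, flags.
#' @return validated data.frame of class `event_log`.
#' @export
event_log <- function(df) {
  needed <- c("subject", "group", "condition", "start_s", "end_s", "flags")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    parse_error(paste("event log missing columns:", paste(missing, collapse = ", ")))
  }
  df <- df[, needed]
  df$flags[is.na(df$flags)] <- ""
  bad <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad)) {
    parse_error(sprintf("unknown condition label(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(df$start_s >= df$end_s)) {
    i <- which(df$start_s >= df$end_s)[1]
    parse_error(sprintf("interval start >= end for subject %s", df$subject[i]), line = i + 1L)
  }
  for (s in unique(df$subject)) {
    e <- df[df$subject == s, , drop = FALSE]
    e <- e[order(e$start_s), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start_s[-1] < e$end_s[-nrow(e)] - 1e-9)) {
      parse_error(sprintf("overlapping intervals for subject %s", s))
    }
    fl <- unlist(strsplit(e$flags[e$flags != ""], ";"))
    badf <- setdiff(fl, EXCLUSION_FLAGS)
    if (length(badf)) {
      parse_error(sprintf("unknown flag(s) '%s' for subject %s", paste(badf, collapse = ","), s))
    }
  }
  class(df) <- c("event_log", "data.frame")
  df
}

empty_event_log <- function() {
  event_log(data.frame(subject = character(0), group = integer(0),
                       condition = character(0), start_s = numeric(0),
                       end_s = numeric(0), flags = character(0),
                       stringsAsFactors = FALSE))
}

read_table_checked <- function(path, expected_cols) {
  if (!file.exists(path)) parse_error("file not found", path = path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header, expected_cols)) {
    parse_error(sprintf("malformed header: expected '%s', found '%s'",
                        paste(expected_cols, collapse = ","),
                        paste(header, collapse = ",")),
                path = path, line = 1L)
  }
  read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
}

#' Read / write one subject's recording
#'
#' The EEG file has columns `time_s,TP9,AF7,AF8,TP10` (uV) and the
#' accelerometer file `time_s,ax,ay,az` (m/s^2). Writing then reading returns
#' the same samples to within float round-off.
#'
#' @param eeg_path,accel_path CSV file paths.
#' @param subject subject id; defaults to the EEG file stem.
#' @return a `recording`.
#' @export
read_recording <- function(eeg_path, accel_path, subject = NULL) {
  if (is.null(subject)) {
    subject <- sub("^recording_", "", sub("\\.csv$", "", basename(eeg_path)))
  }
  n_cols <- length(strsplit(readLines(eeg_path, n = 1L), ",")[[1]])
  if (n_cols != 5L) {
    parse_error(sprintf("expected 5 EEG columns (time_s + 4 channels), found %d", n_cols),
                path = eeg_path, line = 1L)
  }
  eeg <- read_table_checked(eeg_path, c("time_s", CHANNELS))
  acc <- read_table_checked(accel_path, c("time_s", "ax", "ay", "az"))
  for (col in names(eeg)) {
    if (nrow(eeg) > 0 && !is.numeric(eeg[[col]])) {
      parse_error(sprintf("non-numeric values in column '%s'", col), path = eeg_path)
    }
  }
  num_matrix <- function(df, cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    m
  }
  recording(subject,
            num_matrix(eeg, CHANNELS), as.numeric(eeg$time_s),
            num_matrix(acc, c("ax", "ay", "az")), as.numeric(acc$time_s))
}

#' @rdname read_recording
#' @param rec a `recording`.
#' @export
write_recording <- function(rec, eeg_path, accel_path) {
  stopifnot(inherits(rec, "recording"))
  eeg <- data.frame(time_s = rec$eeg_times, rec$eeg, check.names = FALSE)
  acc <- data.frame(time_s = rec$accel_times, rec$accel, check.names = FALSE)
  write.csv(eeg, eeg_path, row.names = FALSE, quote = FALSE)
  write.csv(acc, accel_path, row.names = FALSE, quote = FALSE)
  invisible(c(eeg_path, accel_path))
}

#' Read / write the study event log
#' @param path CSV path with columns subject,group,condition,start_s,end_s,flags.
#' @return an `event_log`.
#' @export
read_event_log <- function(path) {
  df <- read_table_checked(path, c("subject", "group", "condition", "start_s", "end_s", "flags"))
  df$flags[is.na(df$flags)] <- ""
  df$flags <- as.character(df$flags)
  df$subject <- as.character(df$subject)
  event_log(df)
}

#' @rdname read_event_log
#' @param log an `event_log`.
#' @export
write_event_log <- function(log, path) {
  write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the questionnaire table
#'
#' Columns: subject, age (years, 6-88), gender (male/female), occupation,
#' consumption, favorite_piece (1-8), explained (TRUE/FALSE), group.
#' @param path CSV path.
#' @return data.frame, one row per subject.
#' @export
read_questionnaire <- function(path) {
  q <- read_table_checked(path, c("subject", "age", "gender", "occupation",
                                  "consumption", "favorite_piece", "explained", "group"))
  q$subject <- as.character(q$subject)
  validate_questionnaire(q, path)
}

validate_questionnaire <- function(q, path = NULL) {
  if (anyDuplicated(q$subject)) {
    parse_error("duplicated subject ids in questionnaire", path = path)
  }
  if (nrow(q) > 0) {
    if (any(q$age < 6 | q$age > 88)) {
      parse_error("age outside the study range [6, 88]", path = path,
                  line = which(q$age < 6 | q$age > 88)[1] + 1L)
    }
    if (!all(q$gender %in% c("male", "female"))) {
      parse_error("gender must be 'male' or 'female'", path = path)
    }
    if (!all(q$favorite_piece %in% 1:8)) {
      parse_error("favorite_piece must be in 1..8", path = path)
    }
    q$explained <- as.logical(q$explained)
    if (anyNA(q$explained)) parse_error("explained must be TRUE/FALSE", path = path)
  }
  q
}

#' @rdname read_questionnaire
#' @param q questionnaire data.frame.
#' @export
write_questionnaire <- function(q, path) {
  write.csv(q, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a full study dataset as a directory with a YAML manifest
#'
#' Writes `recording_<id>.csv` / `accel_<id>.csv` per subject, `events.csv`,
#' `questionnaire.csv`, a `ground_truth.yaml` sidecar with the planted
#' parameters, and `manifest.yaml` listing everything.
#'
#' @param study a `study_dataset` from [generate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- names(study$recordings)
  files <- lapply(subjects, function(s) {
    ep <- file.path(dir, sprintf("recording_%s.csv", s))
    ap <- file.path(dir, sprintf("accel_%s.csv", s))
    write_recording(study$recordings[[s]], ep, ap)
    list(id = s, recording = basename(ep), accel = basename(ap))
  })
  write_event_log(study$log, file.path(dir, "events.csv"))
  write_questionnaire(study$questionnaire, file.path(dir, "questionnaire.csv"))
  gt <- study$ground_truth
  gt$artifact_intervals <- lapply(gt$artifact_intervals, function(d) {
    list(start_s = d$start_s, end_s = d$end_s)
  })
  gt$segments <- NULL # bulky; regenerate from config + seed when needed
  yaml::write_yaml(gt, file.path(dir, "ground_truth.yaml"))
  manifest <- list(study = "synthetic", subjects = files,
                   events = "events.csv", questionnaire = "questionnaire.csv",
                   ground_truth = "ground_truth.yaml")
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  mp <- file.path(dir, "manifest.yaml")
  if (!file.exists(mp)) parse_error("manifest.yaml not found", path = dir)
  manifest <- yaml::read_yaml(mp)
  recordings <- list()
  for (s in manifest$subjects) {
    recordings[[s$id]] <- read_recording(file.path(dir, s$recording),
                                         file.path(dir, s$accel), subject = s$id)
  }
  log <- read_event_log(file.path(dir, manifest$events))
  q <- read_questionnaire(file.path(dir, manifest$questionnaire))
  gt <- if (!is.null(manifest$ground_truth) &&
            file.exists(file.path(dir, manifest$ground_truth))) {
    yaml::read_yaml(file.path(dir, manifest$ground_truth))
  } else {
    NULL
  }
  structure(list(recordings = recordings, log = log, questionnaire = q,
                 ground_truth = gt, config = NULL),
            class = "study_dataset")
}
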