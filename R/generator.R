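# Synthetic study generator: emulates four-channel mobile EEG plus
# accelerometer recordings, event logs and questionnaires with the statistical
# structure the downstream analysis assumes (1/f background, alpha/beta
# rhythms, a planted frontal beta suppression during favorite-painting
# viewing, a posterior broadband offset, and blink/motion artifacts that
# co-occur with accelerometer excursions).

#' Default favorite-piece probability vectors by gender and age group
#'
#' Eight-piece preference distributions shaped so that the young-adult (18-30)
#' female group favors piece 5 with a top-vs-runner-up margin of about 0.12,
#' the remaining female population favors piece 6 with a margin near 0.09, the
#' young male group favors piece 7 with margin 0.125 and never chooses piece
#' 6, and the remaining male population splits almost evenly between pieces 6
#' and 7.
#'
#' @return Nested list `list(male = list(young, other), female = ...)` of
#'   length-8 probability vectors summing to one.
#' @export
default_favorite_probabilities <- function() {
  list(
    female = list(
      young = c(0.05, 0.05, 0.08, 0.08, 0.30, 0.18, 0.16, 0.10),
      other = c(0.05, 0.05, 0.08, 0.10, 0.15, 0.26, 0.17, 0.14)
    ),
    male = list(
      young = c(0.05, 0.05, 0.10, 0.10, 0.20, 0.00, 0.325, 0.175),
      other = c(0.05, 0.05, 0.08, 0.10, 0.14, 0.25, 0.26, 0.07)
    )
  )
}

#' Configuration for the synthetic study generator
#'
#' Defaults encode the emulated study conditions: 25 analysed subjects, a 60 s
#' eyes-open baseline, eight sequentially viewed pieces of 1-2.2 min each, EEG
#' at 220 samples/s on channels TP9/AF7/AF8/TP10, a three-axis accelerometer
#' at 50 samples/s with a +/- 2 G range, pink (1/f) background EEG with
#' alpha (8-12 Hz) and beta (15-25 Hz) rhythms, a -2 dB beta-band suppression
#' planted on the frontal channels while the subject views their favorite
#' piece, a +3 dB broadband boost on the temporo-parietal channels, and
#' blink/motion artifacts whose EEG deflections exceed 40 uV while the
#' accelerometer simultaneously exceeds 2 m/s^2 on all three axes.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param eeg_rate,accel_rate sampling rates in samples/s.
#' @param baseline_duration baseline (wall-staring) duration in seconds.
#' @param viewing_duration_range min/max viewing duration per piece, seconds.
#' @param background_exponent chi in the 1/f^chi background model.
#' @param background_rms background RMS amplitude over 1-50 Hz, in uV.
#' @param band_amplitudes list with elements `alpha` and `beta`: RMS amplitude
#'   (uV) of the band-limited rhythms.
#' @param beta_suppression_db dB applied to total beta-band power on AF7/AF8
#'   during favorite-piece viewing (negative = suppression).
#' @param posterior_offset_db broadband dB boost on TP9/TP10.
#' @param artifact_rate planted artifact events per minute.
#' @param artifact_amplitude nominal peak EEG deflection of an artifact, uV
#'   (must exceed 40; realised peaks are 0.8-1.5 times this value).
#' @param artifact_accel nominal accelerometer burst peak, m/s^2 (must exceed
#'   2; realised peaks are 1-1.5 times this value on every axis).
#' @param favorite_probabilities nested list as returned by
#'   [default_favorite_probabilities()].
#' @param explained_fraction probability that a whole tour group receives an
#'   explanation of the pieces.
#' @param flag_probability probability that a subject acquires one behavioural
#'   exclusion flag (talking, gum, excessive motion, log inconsistency).
#' @param male_fraction,young_fraction marginal probabilities of being male
#'   and of being in the 18-30 age band.
#' @param occupation_probabilities,consumption_probabilities named probability
#'   vectors for the questionnaire categories.
#' @param accel_jitter_sd resting accelerometer noise, m/s^2.
#' @param group_sizes admissible tour-group sizes.
#'
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 25,
                             seed = 1L,
                             eeg_rate = 220,
                             accel_rate = 50,
                             baseline_duration = 60,
                             viewing_duration_range = c(60, 132),
                             background_exponent = 1,
                             background_rms = 5,
                             band_amplitudes = list(alpha = 4, beta = 3),
                             beta_suppression_db = -2,
                             posterior_offset_db = 3,
                             artifact_rate = 2,
                             artifact_amplitude = 100,
                             artifact_accel = 3,
                             favorite_probabilities = default_favorite_probabilities(),
                             explained_fraction = 0.5,
                             flag_probability = 0.08,
                             male_fraction = 0.41,
                             young_fraction = 0.579,
                             occupation_probabilities = c(student = 0.67, arts = 0.10, other = 0.23),
                             consumption_probabilities = c(rare = 0.41, monthly = 0.30, weekly = 0.26, daily = 0.03),
                             accel_jitter_sd = 0.1,
                             group_sizes = 6:8) {
  cfg <- list(
    n_subjects = n_subjects, seed = as.integer(seed),
    eeg_rate = eeg_rate, accel_rate = accel_rate,
    baseline_duration = baseline_duration,
    viewing_duration_range = viewing_duration_range,
    background_exponent = background_exponent,
    background_rms = background_rms,
    band_amplitudes = band_amplitudes,
    beta_suppression_db = beta_suppression_db,
    posterior_offset_db = posterior_offset_db,
    artifact_rate = artifact_rate,
    artifact_amplitude = artifact_amplitude,
    artifact_accel = artifact_accel,
    favorite_probabilities = favorite_probabilities,
    explained_fraction = explained_fraction,
    flag_probability = flag_probability,
    male_fraction = male_fraction,
    young_fraction = young_fraction,
    occupation_probabilities = occupation_probabilities,
    consumption_probabilities = consumption_probabilities,
    accel_jitter_sd = accel_jitter_sd,
    group_sizes = group_sizes,
    bands = list(alpha = c(8, 12), beta = c(15, 25))
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  for (nm in c("eeg_rate", "accel_rate", "baseline_duration", "background_rms")) {
    stopifnot_scalar_number(cfg[[nm]], nm)
  }
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 0 ||
      cfg$n_subjects != round(cfg$n_subjects)) {
    validation_error("'n_subjects' must be a non-negative integer")
  }
  if (length(cfg$viewing_duration_range) != 2L ||
      any(cfg$viewing_duration_range <= 0) ||
      diff(cfg$viewing_duration_range) < 0) {
    validation_error("'viewing_duration_range' must be positive and increasing")
  }
  if (cfg$artifact_rate < 0) validation_error("'artifact_rate' must be >= 0")
  if (cfg$artifact_amplitude <= 40) {
    validation_error("'artifact_amplitude' must exceed the 40 uV screening threshold")
  }
  if (cfg$artifact_accel <= 2) {
    validation_error("'artifact_accel' must exceed the 2 m/s^2 screening threshold")
  }
  nyq <- cfg$eeg_rate / 2
  for (b in names(cfg$bands)) {
    band <- cfg$bands[[b]]
    if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2]) {
      validation_error(sprintf("band '%s' must lie strictly inside (0, %g) Hz", b, nyq))
    }
  }
  if (any(unlist(cfg$band_amplitudes) < 0)) {
    validation_error("band amplitudes must be non-negative")
  }
  for (g in c("male", "female")) {
    for (a in c("young", "other")) {
      p <- cfg$favorite_probabilities[[g]][[a]]
      if (length(p) != 8L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        validation_error(sprintf(
          "favorite_probabilities$%s$%s must be 8 non-negative values summing to 1", g, a))
      }
    }
  }
  for (nm in c("occupation_probabilities", "consumption_probabilities")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      validation_error(sprintf("'%s' must sum to 1", nm))
    }
  }
  for (nm in c("explained_fraction", "flag_probability", "male_fraction", "young_fraction")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      validation_error(sprintf("'%s' must lie in [0, 1]", nm))
    }
  }
  cfg
}

# Two-sided target PSD (uV^2/Hz) on the FFT grid of a segment of n samples.
# `fold` is the magnitude-frequency of every bin. Condition effects are
# applied multiplicatively: `band_gains_db` is a named list band -> dB applied
# to total in-band power, `broad_gain_db` applies everywhere.
segment_psd <- function(n, fs, cfg, broad_gain_db = 0, band_gains_db = list()) {
  f <- (seq_len(n) - 1) * fs / n
  fold <- pmin(f, fs - f)
  df <- fs / n
  s <- numeric(n)
  if (cfg$background_rms > 0) {
    g <- 1 / pmax(fold, 1)^cfg$background_exponent
    g[1] <- 0 # zero-mean signal
    sel <- fold >= 1 & fold <= 50
    norm <- sum(g[sel]) * df
    if (norm > 0) s <- s + cfg$background_rms^2 * g / norm
  }
  for (b in names(cfg$bands)) {
    amp <- cfg$band_amplitudes[[b]] %||% 0
    if (amp > 0) {
      lo <- cfg$bands[[b]][1]; hi <- cfg$bands[[b]][2]
      h <- numeric(n)
      inb <- fold >= lo & fold <= hi
      h[inb] <- 0.5 * (1 - cos(2 * pi * (fold[inb] - lo) / (hi - lo)))
      tot <- sum(h) * df
      if (tot > 0) s <- s + amp^2 * h / tot
    }
  }
  s <- s * 10^(broad_gain_db / 10)
  for (b in names(band_gains_db)) {
    lo <- cfg$bands[[b]][1]; hi <- cfg$bands[[b]][2]
    inb <- fold >= lo & fold <= hi
    s[inb] <- s[inb] * 10^(band_gains_db[[b]] / 10)
  }
  s[1] <- 0
  s
}

# Colored-noise synthesis by spectral shaping of white noise; returns a real
# series whose PSD matches the two-sided density `s2` (uV^2/Hz).
synth_colored <- function(n, fs, s2) {
  if (n == 0L) return(numeric(0))
  w <- rnorm(n)
  amp <- sqrt(fs * s2)
  Re(fft(fft(w) * amp, inverse = TRUE) / n)
}

#' Generate one subject's synchronized EEG + accelerometer recording
#'
#' Each logged interval (and the transit gaps between intervals) is
#' synthesized independently by spectral shaping: a 1/f^chi background plus
#' Hann-shaped alpha and beta spectral bumps. During viewing of
#' `favorite_piece` the total beta-band power on AF7 and AF8 is multiplied by
#' `beta_suppression_db`; TP9 and TP10 carry `posterior_offset_db` extra
#' broadband power throughout. Planted artifacts are simultaneous biphasic
#' EEG deflections exceeding the 40 uV screening threshold and raised-cosine
#' accelerometer bursts exceeding 2 m/s^2 on all three axes; the
#' accelerometer is clipped to the +/- 2 G device range.
#'
#' @param config a [generator_config()].
#' @param subject subject identifier (string).
#' @param log an event log (see [event_log()]) whose intervals cover the
#'   baseline and the eight viewing segments for this subject.
#' @param favorite_piece the piece label (e.g. `"P5"`) during which the
#'   frontal beta suppression is planted, or `NULL` for no planted effect.
#' @return A `recording` object; attribute `"ground_truth"` carries planted
#'   artifact intervals and the per-segment spectral parameters.
#' @export
generate_recording <- function(config, subject, log, favorite_piece = NULL) {
  config <- validate_generator_config(config)
  entries <- log[log$subject == subject, , drop = FALSE]
  if (nrow(entries) == 0L) validation_error(sprintf("no log entries for subject '%s'", subject))
  entries <- entries[order(entries$start_s), , drop = FALSE]
  set.seed(subject_seed(config$seed, subject))

  fs <- config$eeg_rate
  fa <- config$accel_rate
  t_end <- max(entries$end_s)
  n_eeg <- floor(t_end * fs) + 1L
  n_acc <- floor(t_end * fa) + 1L
  eeg_times <- (seq_len(n_eeg) - 1) / fs
  accel_times <- (seq_len(n_acc) - 1) / fa

  # segment table: logged intervals plus unlabeled transit gaps
  segs <- data.frame(start = entries$start_s, end = entries$end_s,
                     condition = entries$condition, stringsAsFactors = FALSE)
  gaps <- data.frame(start = numeric(0), end = numeric(0), condition = character(0))
  cur <- 0
  for (i in seq_len(nrow(segs))) {
    if (segs$start[i] > cur + 1e-9) {
      gaps <- rbind(gaps, data.frame(start = cur, end = segs$start[i], condition = "transit"))
    }
    cur <- segs$end[i]
  }
  segs <- rbind(segs, gaps)
  segs <- segs[order(segs$start), , drop = FALSE]

  eeg <- matrix(0, n_eeg, 4, dimnames = list(NULL, CHANNELS))
  seg_truth <- NULL
  for (i in seq_len(nrow(segs))) {
    idx <- which(eeg_times >= segs$start[i] - 1e-12 & eeg_times < segs$end[i] - 1e-12)
    if (i == nrow(segs)) idx <- which(eeg_times >= segs$start[i] - 1e-12)
    n <- length(idx)
    if (n == 0L) next
    fp_here <- !is.null(favorite_piece) && identical(segs$condition[i], favorite_piece)
    for (ch in CHANNELS) {
      broad <- if (ch %in% POSTERIOR) config$posterior_offset_db else 0
      gains <- if (fp_here && ch %in% FRONTAL) {
        list(beta = config$beta_suppression_db)
      } else {
        list()
      }
      s2 <- segment_psd(n, fs, config, broad_gain_db = broad, band_gains_db = gains)
      eeg[idx, ch] <- synth_colored(n, fs, s2)
      seg_truth <- rbind(seg_truth, data.frame(
        subject = subject, condition = segs$condition[i], channel = ch,
        start_s = segs$start[i], end_s = segs$end[i],
        beta_gain_db = if (fp_here && ch %in% FRONTAL) config$beta_suppression_db else 0,
        broad_gain_db = broad, stringsAsFactors = FALSE))
    }
  }

  accel <- matrix(rnorm(n_acc * 3, sd = config$accel_jitter_sd), n_acc, 3,
                  dimnames = list(NULL, c("ax", "ay", "az")))

  # planted artifacts: simultaneous EEG deflection + tri-axial accel burst
  artifacts <- data.frame(start_s = numeric(0), end_s = numeric(0))
  n_art <- if (config$artifact_rate > 0) rpois(1, config$artifact_rate * t_end / 60) else 0L
  if (n_art > 0) {
    at <- sort(runif(n_art, 1, t_end - 1))
    blink_n <- round(0.3 * fs)
    blink_shape <- sin(2 * pi * seq(0, 1, length.out = blink_n)) *
      0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = blink_n)))
    blink_shape <- blink_shape / max(abs(blink_shape))
    burst_n <- round(0.5 * fa)
    burst_env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = burst_n)))
    for (tt in at) {
      amp <- config$artifact_amplitude * runif(1, 0.8, 1.5) * sample(c(-1, 1), 1)
      i0 <- floor((tt - 0.15) * fs) + 1L
      ii <- i0:(i0 + blink_n - 1L)
      ok <- ii >= 1L & ii <= n_eeg
      for (ch in FRONTAL) eeg[ii[ok], ch] <- eeg[ii[ok], ch] + amp * blink_shape[ok]
      j0 <- floor((tt - 0.25) * fa) + 1L
      jj <- j0:(j0 + burst_n - 1L)
      okj <- jj >= 1L & jj <= n_acc
      peaks <- config$artifact_accel * runif(3, 1.0, 1.5) * sample(c(-1, 1), 3, replace = TRUE)
      for (ax in 1:3) accel[jj[okj], ax] <- accel[jj[okj], ax] + peaks[ax] * burst_env[okj]
      artifacts <- rbind(artifacts, data.frame(start_s = tt - 0.25, end_s = tt + 0.25))
    }
  }
  accel <- pmin(pmax(accel, -2 * GRAVITY), 2 * GRAVITY)

  rec <- recording(subject, eeg, eeg_times, accel, accel_times,
                   eeg_rate = fs, accel_rate = fa)
  attr(rec, "ground_truth") <- list(artifact_intervals = artifacts, segments = seg_truth)
  rec
}

#' Generate a complete synthetic study dataset
#'
#' Draws a questionnaire (age, gender, occupation, art-consumption frequency,
#' favorite piece, explanation flag assigned to whole tour groups), builds a
#' per-subject event log (baseline followed by eight sequential viewings with
#' short transit gaps, occasionally flagged with behavioural exclusion
#' reasons), and synthesizes every subject's recording with the planted
#' effects of [generate_recording()].
#'
#' @param config a [generator_config()].
#' @param include_recordings synthesize the EEG/accelerometer streams; set to
#'   `FALSE` for questionnaire/log-only studies (e.g. large demographic
#'   cohorts).
#' @return A list of class `study_dataset` with elements `recordings` (named
#'   list), `log` (event log for all subjects), `questionnaire` (one row per
#'   subject), and `ground_truth` (planted parameters for test oracles).
#' @export
generate_study <- function(config = generator_config(), include_recordings = TRUE) {
  config <- validate_generator_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_subjects)
  subjects <- if (n > 0) sprintf("S%03d", seq_len(n)) else character(0)

  # tour groups of 6-8 subjects; explanation is a group-level property
  group <- integer(n)
  gid <- 0L
  i <- 1L
  while (i <= n) {
    gid <- gid + 1L
    size <- sample(config$group_sizes, 1)
    group[i:min(n, i + size - 1L)] <- gid
    i <- i + size
  }
  # tours of both types are scheduled deliberately: exactly this fraction of
  # groups (rounded) receives an explanation, in a random arrangement
  n_groups <- if (n > 0) max(group) else 0L
  explained_groups <- logical(n_groups)
  if (n_groups > 0) {
    n_e <- round(n_groups * config$explained_fraction)
    explained_groups[sample.int(n_groups, n_e)] <- TRUE
  }

  young <- as.logical(rbinom(n, 1, config$young_fraction))
  age <- integer(n)
  age[young] <- sample(18:30, sum(young), replace = TRUE)
  age[!young] <- sample(c(6:17, 31:88), sum(!young), replace = TRUE)
  gender <- ifelse(as.logical(rbinom(n, 1, config$male_fraction)), "male", "female")
  occupation <- if (n > 0) {
    sample(names(config$occupation_probabilities), n, replace = TRUE,
           prob = config$occupation_probabilities)
  } else {
    character(0)
  }
  consumption <- if (n > 0) {
    sample(names(config$consumption_probabilities), n, replace = TRUE,
           prob = config$consumption_probabilities)
  } else {
    character(0)
  }
  favorite <- integer(n)
  for (i in seq_len(n)) {
    grp <- if (age[i] >= 18 && age[i] <= 30) "young" else "other"
    favorite[i] <- sample(1:8, 1, prob = config$favorite_probabilities[[gender[i]]][[grp]])
  }
  questionnaire <- data.frame(
    subject = subjects, age = age, gender = gender, occupation = occupation,
    consumption = consumption, favorite_piece = favorite,
    explained = if (n > 0) explained_groups[group] else logical(0),
    group = group, stringsAsFactors = FALSE
  )

  # event logs: baseline then eight pieces in order, 5 s transit gaps
  log_rows <- vector("list", n)
  for (i in seq_len(n)) {
    durations <- runif(8, config$viewing_duration_range[1], config$viewing_duration_range[2])
    start <- config$baseline_duration + 5
    rows <- data.frame(subject = subjects[i], group = group[i], condition = "BL",
                       start_s = 0, end_s = config$baseline_duration, flags = "",
                       stringsAsFactors = FALSE)
    for (p in 1:8) {
      rows <- rbind(rows, data.frame(
        subject = subjects[i], group = group[i], condition = PIECES[p],
        start_s = start, end_s = start + durations[p], flags = "",
        stringsAsFactors = FALSE))
      start <- start + durations[p] + 5
    }
    if (runif(1) < config$flag_probability) {
      j <- sample(2:9, 1)
      rows$flags[j] <- sample(EXCLUSION_FLAGS, 1)
    }
    log_rows[[i]] <- rows
  }
  log <- if (n > 0) event_log(do.call(rbind, log_rows)) else empty_event_log()

  recordings <- list()
  ground_truth <- list(artifact_intervals = list(), segments = list(),
                       planted = list(beta_suppression_db = config$beta_suppression_db,
                                      posterior_offset_db = config$posterior_offset_db,
                                      bands = config$bands))
  for (i in seq_len(if (include_recordings) n else 0L)) {
    rec <- generate_recording(config, subjects[i], log,
                              favorite_piece = PIECES[favorite[i]])
    gt <- attr(rec, "ground_truth")
    ground_truth$artifact_intervals[[subjects[i]]] <- gt$artifact_intervals
    ground_truth$segments[[subjects[i]]] <- gt$segments
    attr(rec, "ground_truth") <- NULL
    recordings[[subjects[i]]] <- rec
  }

  structure(
    list(recordings = recordings, log = log, questionnaire = questionnaire,
         ground_truth = ground_truth, config = config),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Synthetic study dataset: %d subjects, %d log entries\n",
              length(x$recordings), nrow(x$log)))
  invisible(x)
}
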