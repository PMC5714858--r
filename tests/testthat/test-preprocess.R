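test_that("band-pass filter removes DC and attenuates out-of-band tones", {
  n <- 2200
  t <- (seq_len(n) - 1) / 220
  trim <- 221:(n - 220) # drop edge transients

  const <- bandpass_filter(rep(10, n), 220)
  expect_lt(max(abs(const[trim])), 0.1)

  in_band <- bandpass_filter(sin(2 * pi * 10 * t), 220)
  out_band <- bandpass_filter(sin(2 * pi * 60 * t), 220)
  rms <- function(x) sqrt(mean(x^2))
  atten_db <- 20 * log10(rms(in_band[trim]) / rms(out_band[trim]))
  expect_gte(atten_db, 20)
})

test_that("filtering is zero-phase: commutes with time reversal", {
  set.seed(1)
  x <- rnorm(1100)
  a <- bandpass_filter(rev(x), 220)
  b <- rev(bandpass_filter(x, 220))
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("filter rejects bad bands and too-short signals", {
  expect_error(bandpass_filter(rnorm(500), 220, low = 0, high = 50), "band edges")
  expect_error(bandpass_filter(rnorm(500), 220, low = 40, high = 10), "band edges")
  expect_error(bandpass_filter(rnorm(10), 220), "too short")
})

test_that("subject screening excludes exactly the flagged subjects", {
  log <- event_log(data.frame(
    subject = c("S1", "S1", "S2", "S3", "S3"), group = 1,
    condition = c("BL", "P1", "BL", "P1", "P2"),
    start_s = c(0, 70, 0, 70, 140), end_s = c(60, 130, 60, 130, 200),
    flags = c("", "", "", "gum", "talking;gum")))
  ex <- screen_subjects(log)
  expect_equal(nrow(ex), 1)
  expect_equal(ex$subject, "S3")
  expect_equal(ex$reasons, "gum;talking")

  clean <- log
  clean$flags <- ""
  expect_equal(nrow(screen_subjects(event_log(clean))), 0)
})

test_that("artifact screen applies thresholds with the all-axes rule", {
  n <- 1100 # 5 s of EEG, 250 accel samples
  eeg <- matrix(0, n, 4)
  accel <- matrix(0, 250, 3)

  rec <- make_recording(eeg, accel)
  m <- detect_artifacts(rec)
  expect_false(any(m$mask))

  # tri-axial excursion at t = 2 s flags the aligned EEG span
  accel_hit <- accel
  accel_hit[101, ] <- c(2.5, 2.1, 3.0)
  rec <- make_recording(eeg, accel_hit)
  m <- detect_artifacts(rec)
  expect_true(any(m$mask))
  expect_true(all(grepl("acceleration", m$runs$reason)))
  flagged_t <- rec$eeg_times[m$mask]
  # accel sample covers [2, 2.02) of EEG; dilation adds 0.5 s each side
  expect_true(all(abs(flagged_t - 2) <= 0.55))

  # one quiet axis: not an artifact under the conjunctive rule...
  accel_partial <- accel
  accel_partial[101, ] <- c(2.5, 0.0, 3.0)
  rec <- make_recording(eeg, accel_partial)
  expect_false(any(detect_artifacts(rec)$mask))
  # ...but flagged under the disjunctive option
  expect_true(any(detect_artifacts(rec, axis_rule = "any")$mask))
})

test_that("amplitude criterion flags any channel over threshold, post-filter", {
  n <- 2200
  t <- (seq_len(n) - 1) / 220
  eeg <- matrix(0, n, 4)
  eeg[, 2] <- 50 * sin(2 * pi * 10 * t) # in-band, 50 uV > 40 uV on AF7
  rec <- make_recording(eeg)
  m <- detect_artifacts(rec)
  expect_true(any(m$mask))
  expect_true(any(grepl("amplitude", m$runs$reason)))
  expect_error(detect_artifacts(make_recording(eeg, matrix(0, 0, 3))),
               "accelerometer stream required")
})

test_that("lowering either threshold never decreases the flagged count", {
  cfg <- tiny_generator(seed = 21, n_subjects = 1, artifact_rate = 4)
  st <- generate_study(cfg)
  rec <- st$recordings$S001
  filt <- bandpass_filter(rec$eeg, rec$eeg_rate)
  base <- sum(detect_artifacts(rec, filtered = filt)$mask)
  lower_amp <- sum(detect_artifacts(rec, amp_thresh = 25, filtered = filt)$mask)
  lower_acc <- sum(detect_artifacts(rec, accel_thresh = 1, filtered = filt)$mask)
  expect_gte(lower_amp, base)
  expect_gte(lower_acc, base)
})

test_that("epoch tiling is centered in the longest clean run", {
  # 1300 clean samples: 5 non-overlapping 256-windows, first start offset 10
  eeg <- matrix(rnorm(1300 * 4), 1300, 4)
  rec <- make_recording(eeg)
  log <- one_interval_log("T01", "BL", 0, 1300 / 220)
  ep <- extract_epochs(rec, NULL, log)
  expect_equal(nrow(ep$data), 5 * 4)
  starts <- sort(unique(ep$labels$start_s)) * 220
  expect_equal(round(starts), c(10, 266, 522, 778, 1034))
  expect_equal(ep$duration_s, 256 / 220, tolerance = 1e-12)

  # too-short run: zero epochs
  rec2 <- make_recording(matrix(0, 200, 4))
  ep2 <- extract_epochs(rec2, NULL, one_interval_log("T01", "BL", 0, 200 / 220))
  expect_equal(nrow(ep2$data), 0)
})

test_that("overlap option increases epoch yield as expected", {
  eeg <- matrix(rnorm(1300 * 4), 1300, 4)
  rec <- make_recording(eeg)
  log <- one_interval_log("T01", "BL", 0, 1300 / 220)
  ep50 <- extract_epochs(rec, NULL, log, overlap = 0.5)
  # step 128: (1300 - 256) %/% 128 + 1 = 9 windows per channel
  expect_equal(nrow(ep50$data), 9 * 4)
})

test_that("no epoch overlaps a flagged sample and counts follow the tiling formula", {
  cfg <- tiny_generator(seed = 22, n_subjects = 1, artifact_rate = 3)
  st <- generate_study(cfg)
  rec <- st$recordings$S001
  filt <- bandpass_filter(rec$eeg, rec$eeg_rate)
  mask <- detect_artifacts(rec, filtered = filt)
  ep <- extract_epochs(rec, mask, st$log, data = filt)
  if (nrow(ep$data) > 0) {
    for (i in seq_len(nrow(ep$labels))) {
      i0 <- which.min(abs(rec$eeg_times - ep$labels$start_s[i]))
      expect_false(any(mask$mask[i0:(i0 + 255)]))
    }
  }
  # with no artifacts the per-interval count is the closed-form tiling count
  cfg0 <- tiny_generator(seed = 23, n_subjects = 1, artifact_rate = 0,
                         background_rms = 2, band_amplitudes = list(alpha = 1, beta = 1))
  st0 <- generate_study(cfg0)
  rec0 <- st0$recordings$S001
  ep0 <- extract_epochs(rec0, NULL, st0$log)
  entries <- st0$log[st0$log$subject == "S001", ]
  expected <- sum(vapply(seq_len(nrow(entries)), function(i) {
    len <- sum(rec0$eeg_times >= entries$start_s[i] - 1e-12 &
                 rec0$eeg_times < entries$end_s[i] - 1e-12)
    max((len - 256) %/% 256 + 1, 0)
  }, numeric(1)))
  expect_equal(nrow(ep0$data), expected * 4)
})
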