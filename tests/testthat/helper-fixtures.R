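# Shared fixtures: all synthetic, built in code at test time.

channels <- c("TP9", "AF7", "AF8", "TP10")

# A recording assembled from explicit sample matrices at the nominal rates.
make_recording <- function(eeg, accel = NULL, subject = "T01",
                           eeg_rate = 220, accel_rate = 50) {
  eeg <- as.matrix(eeg)
  n <- nrow(eeg)
  t_end <- n / eeg_rate
  if (is.null(accel)) {
    m <- floor(t_end * accel_rate) + 1L
    accel <- matrix(0, m, 3)
  }
  recording(subject, eeg, (seq_len(n) - 1) / eeg_rate,
            accel, (seq_len(nrow(accel)) - 1) / accel_rate,
            eeg_rate = eeg_rate, accel_rate = accel_rate)
}

# A single-subject log covering one interval.
one_interval_log <- function(subject = "T01", condition = "BL",
                             start = 0, end = 10, flags = "") {
  event_log(data.frame(subject = subject, group = 1L, condition = condition,
                       start_s = start, end_s = end, flags = flags,
                       stringsAsFactors = FALSE))
}

# Small fast generator configuration for pipeline-level tests.
tiny_generator <- function(seed = 1, n_subjects = 3, ...) {
  args <- list(n_subjects = n_subjects, seed = seed,
               baseline_duration = 30,
               viewing_duration_range = c(20, 25),
               flag_probability = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

# Brute-force Calinski-Harabasz evaluation: double loop over points,
# independent of the package implementation.
brute_ch <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  ks <- sort(unique(labels))
  K <- length(ks)
  gm <- colMeans(X)
  W <- 0
  B <- 0
  for (k in ks) {
    rows <- which(labels == k)
    ck <- colMeans(X[rows, , drop = FALSE])
    for (i in rows) W <- W + sum((X[i, ] - ck)^2)
    B <- B + length(rows) * sum((ck - gm)^2)
  }
  (B / (K - 1)) / (W / (n - K))
}

# Two-template 60-dimensional spectral-like vectors: templates a fixed
# distance apart (in units of per-coordinate noise sd).
make_two_template <- function(n_per = 50, d = 60, distance = 6, sd = 1,
                              seed = 1) {
  set.seed(seed)
  t1 <- rnorm(d)
  dir <- rnorm(d)
  dir <- dir / sqrt(sum(dir^2))
  t2 <- t1 + distance * sd * dir
  X <- rbind(
    matrix(rnorm(n_per * d, sd = sd), n_per, d, byrow = TRUE) + rep(t1, each = n_per),
    matrix(rnorm(n_per * d, sd = sd), n_per, d, byrow = TRUE) + rep(t2, each = n_per)
  )
  list(X = X, truth = rep(1:2, each = n_per))
}
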