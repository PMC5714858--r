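# Thomson multitaper spectral estimation and the 60-dimensional
# baseline-corrected log-power vectors used by clustering and band statistics.

#' Frequency band definition
#'
#' @param name band name.
#' @param lo,hi band edges in Hz.
#' @return list of class `band_definition`.
#' @export
band_definition <- function(name, lo, hi) {
  if (!(lo < hi)) validation_error("band must satisfy lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' Default analysis bands: alpha 8-12 Hz, beta 15-25 Hz, broad 1-50 Hz
#' @return named list of [band_definition()]s.
#' @export
default_bands <- function() {
  list(alpha = band_definition("alpha", 8, 12),
       beta = band_definition("beta", 15, 25),
       broad = band_definition("broad", 1, 50))
}

# DPSS (Slepian) tapers via the symmetric tridiagonal eigenproblem; unit
# energy, cached per (n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (DPSS) tapers
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 4).
#' @param k number of tapers (default `2 * nw - 1 = 7`).
#' @return n x k matrix of unit-energy tapers, in decreasing order of
#'   spectral concentration.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  if (k >= n) validation_error("need k < n tapers")
  w <- nw / n
  t_ <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_) / 2)^2 * cos(2 * pi * w)
  diag_off <- t_[-1] * (n - t_[-1]) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(seq_len(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, seq_len(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # conventional polarity: symmetric tapers positive mean, antisymmetric
  # tapers positive initial slope (polarity does not affect the PSD)
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tapers[, j] <- -tapers[, j]
    } else if (tapers[2, j] < tapers[1, j]) {
      tapers[, j] <- -tapers[, j]
    }
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

#' Thomson multitaper power spectral density of one epoch
#'
#' Averages the spectrograms of the epoch windowed by `k` unit-energy DPSS
#' tapers. The one-sided estimate integrates to the epoch's mean square value
#' (uV^2) over the grid, i.e. units are uV^2/Hz.
#'
#' @param epoch numeric vector (finite values).
#' @param rate sampling rate, samples/s.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return list with `freq` (Hz, `0 .. rate/2` on the n-point grid) and `psd`
#'   (one-sided, nonnegative).
#' @export
multitaper_psd <- function(epoch, rate = 220, nw = 4, k = 2 * nw - 1) {
  if (anyNA(epoch) || any(!is.finite(epoch))) {
    validation_error("epoch contains NA or non-finite values")
  }
  p <- psd_matrix(matrix(epoch, nrow = 1), rate = rate, nw = nw, k = k)
  n <- length(epoch)
  list(freq = (0:(n %/% 2)) * rate / n, psd = p[1, ])
}

# Vectorized multitaper over the rows of an epoch matrix. Returns
# n_epochs x (window/2 + 1) one-sided PSDs.
psd_matrix <- function(data, rate = 220, nw = 4, k = 2 * nw - 1) {
  n <- ncol(data)
  n_ep <- nrow(data)
  tapers <- dpss_tapers(n, nw, k)
  half <- n %/% 2
  acc <- matrix(0, half + 1L, n_ep)
  xt <- t(data)
  for (j in seq_len(k)) {
    F <- mvfft(xt * tapers[, j])
    acc <- acc + Mod(F[seq_len(half + 1L), , drop = FALSE])^2
  }
  psd <- acc / (k * rate)
  # one-sided: double every bin that has a negative-frequency twin
  interior <- 2:(half + if (n %% 2 == 0) 0L else 1L)
  psd[interior, ] <- 2 * psd[interior, ]
  t(psd)
}

#' Baseline bank: mean BL log-spectra for baseline correction
#'
#' Averages `10 log10` power over baseline epochs, grouped according to
#' `mode`: `"subject-sensor"` keeps each (subject, sensor) pair separate;
#' `"subject"` (the pipeline default) pools a subject's four sensors so that
#' sensor topography survives correction; `"global"` uses one grand-mean
#' spectrum. The bank is keyed by (subject, sensor) in every mode.
#'
#' @param logp matrix of baseline log-power rows (dB), n_bl_epochs x n_bins.
#' @param labels data.frame with `subject` and `sensor` for each row.
#' @param mode grouping mode.
#' @param subjects,sensors key space to populate (defaults: those in labels /
#'   all four channels).
#' @return named list `"subject|sensor"` -> mean log-spectrum.
#' @export
baseline_bank <- function(logp, labels,
                          mode = c("subject", "subject-sensor", "global"),
                          subjects = unique(labels$subject), sensors = CHANNELS) {
  mode <- match.arg(mode)
  if (nrow(logp) == 0L) validation_error("no baseline epochs to build a bank from")
  bank <- list()
  if (mode == "global") {
    m <- colMeans(logp)
    for (s in subjects) for (ch in sensors) bank[[paste(s, ch, sep = "|")]] <- m
  } else if (mode == "subject") {
    for (s in subjects) {
      rows <- labels$subject == s
      if (!any(rows)) next
      m <- colMeans(logp[rows, , drop = FALSE])
      for (ch in sensors) bank[[paste(s, ch, sep = "|")]] <- m
    }
  } else {
    for (s in subjects) {
      for (ch in sensors) {
        rows <- labels$subject == s & labels$sensor == ch
        if (!any(rows)) next
        bank[[paste(s, ch, sep = "|")]] <- colMeans(logp[rows, , drop = FALSE])
      }
    }
  }
  bank
}

#' Baseline-correct one raw spectrum into a 60-dimensional vector
#'
#' `values = 10 log10(psd) - bank[[subject|sensor]]`, truncated to the first
#' 60 positive-frequency bins (0.86-51.56 Hz at 220 samples/s, 256-point
#' grid).
#'
#' @param psd one-sided raw spectrum as returned by [multitaper_psd()]
#'   (including the DC bin).
#' @param subject,sensor key into the bank.
#' @param bank a [baseline_bank()].
#' @param rate,n_fft grid parameters.
#' @param n_bins vector dimension.
#' @return list of class `spectral_vector` with `values` (dB), `freqs` (Hz),
#'   `corrected = TRUE`.
#' @export
baseline_correct <- function(psd, subject, sensor, bank, rate = 220,
                             n_fft = 256, n_bins = 60) {
  key <- paste(subject, sensor, sep = "|")
  if (is.null(bank[[key]])) {
    validation_error(sprintf("no baseline spectrum for subject '%s', sensor '%s'",
                             subject, sensor))
  }
  if (is.list(psd)) psd <- psd$psd
  raw <- 10 * log10(psd[2:(n_bins + 1L)])
  structure(list(values = raw - bank[[key]][seq_len(n_bins)],
                 freqs = (seq_len(n_bins)) * rate / n_fft,
                 labels = list(subject = subject, sensor = sensor),
                 corrected = TRUE),
            class = "spectral_vector")
}

#' Spectral vectors for a whole epoch set
#'
#' Computes the multitaper PSD of every epoch, truncates to the first
#' `n_bins` positive-frequency bins, converts to dB and (optionally)
#' subtracts a baseline bank built from the BL-labeled epochs.
#'
#' @param epochs an `epoch_set`.
#' @param nw,k multitaper parameters.
#' @param n_bins vector dimension (default 60).
#' @param baseline `"subject"`, `"subject-sensor"`, `"global"` or `"none"`.
#' @param bank optional precomputed [baseline_bank()]; overrides `baseline`.
#' @return object of class `spectral_set`: `values` (n_epochs x n_bins dB
#'   matrix), `freqs`, `labels` (copied from the epoch set), `corrected`,
#'   `bank`.
#' @export
spectral_dataset <- function(epochs, nw = 4, k = 2 * nw - 1, n_bins = 60,
                             baseline = c("subject", "subject-sensor",
                                          "global", "none"),
                             bank = NULL) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(epochs, "epoch_set"))
  psd <- psd_matrix(epochs$data, rate = epochs$rate, nw = nw, k = k)
  logp <- 10 * log10(psd[, 2:(n_bins + 1L), drop = FALSE])
  freqs <- seq_len(n_bins) * epochs$rate / epochs$window
  corrected <- FALSE
  if (is.null(bank) && baseline != "none") {
    bl <- epochs$labels$condition == "BL"
    if (!any(bl)) validation_error("no BL epochs available to build a baseline bank")
    bank <- baseline_bank(logp[bl, , drop = FALSE], epochs$labels[bl, , drop = FALSE],
                          mode = baseline)
  }
  if (!is.null(bank)) {
    keys <- paste(epochs$labels$subject, epochs$labels$sensor, sep = "|")
    miss <- setdiff(unique(keys), names(bank))
    if (length(miss)) {
      validation_error(paste("missing baseline spectra for:", paste(miss, collapse = ", ")))
    }
    ref <- do.call(rbind, bank[keys])
    logp <- logp - ref[, seq_len(n_bins), drop = FALSE]
    corrected <- TRUE
  }
  structure(list(values = logp, freqs = freqs, labels = epochs$labels,
                 corrected = corrected, bank = bank),
            class = "spectral_set")
}

#' @export
print.spectral_set <- function(x, ...) {
  cat(sprintf("Spectral set: %d vectors x %d bins (%.2f-%.2f Hz), %s\n",
              nrow(x$values), ncol(x$values), min(x$freqs), max(x$freqs),
              if (x$corrected) "baseline-corrected" else "raw"))
  invisible(x)
}

#' Mean band power of spectral vectors
#'
#' Mean of the log-power coefficients whose center frequency lies inside the
#' band (inclusive).
#'
#' @param x a `spectral_set`, `spectral_vector`, or numeric matrix/vector of
#'   coefficients.
#' @param band a [band_definition()].
#' @param freqs frequency grid (required when `x` is a bare matrix/vector).
#' @return numeric vector of per-epoch band powers (dB), or a scalar for a
#'   single vector.
#' @export
band_power <- function(x, band, freqs = NULL) {
  stopifnot(inherits(band, "band_definition"))
  if (inherits(x, "spectral_set")) {
    freqs <- x$freqs; vals <- x$values
  } else if (inherits(x, "spectral_vector")) {
    freqs <- x$freqs; vals <- matrix(x$values, nrow = 1)
  } else {
    if (is.null(freqs)) validation_error("'freqs' required for a bare matrix")
    vals <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  }
  sel <- freqs >= band$lo & freqs <= band$hi
  if (!any(sel)) {
    validation_error(sprintf("band '%s' (%g-%g Hz) does not overlap the grid",
                             band$name, band$lo, band$hi))
  }
  out <- rowMeans(vals[, sel, drop = FALSE])
  if (length(out) == 1L && !is.matrix(x) && !inherits(x, "spectral_set")) out[[1]] else out
}
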