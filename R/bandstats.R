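# Band-wise condition contrasts: per-sensor two-sample t-tests on per-epoch
# band powers, averaged p-values across sensors, the seeded random
# non-favorite-painting control, and 90%-of-data envelope curves.

#' Two-sample t-test on band-power scalars
#'
#' Welch's unequal-variance test by default (set `var_equal = TRUE` for the
#' pooled-variance variant). When both groups are constant and equal the
#' p-value is 1 by convention (0 when constant but different).
#'
#' @param a,b numeric vectors of per-epoch band powers (dB), each length >= 2.
#' @param var_equal pooled-variance test instead of Welch.
#' @return list: `p`, `effect` (= mean(a) - mean(b), dB), `t`, `df`,
#'   `n = c(length(a), length(b))`.
#' @export
band_ttest <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    validation_error("each group needs at least 2 values")
  }
  effect <- mean(a) - mean(b)
  if (sd(a) == 0 && sd(b) == 0) {
    return(list(p = if (effect == 0) 1 else 0, effect = effect,
                t = if (effect == 0) 0 else Inf * sign(effect),
                df = NA_real_, n = c(length(a), length(b))))
  }
  ht <- t.test(a, b, var.equal = var_equal)
  list(p = unname(ht$p.value), effect = effect, t = unname(ht$statistic),
       df = unname(ht$parameter), n = c(length(a), length(b)))
}

#' Band-restricted condition contrast across sensors
#'
#' For each band and each sensor, reduces epochs to per-epoch mean band power
#' and runs an independent two-sample t-test between the two spectral sets;
#' the across-sensor average p-value per band is the arithmetic mean of the
#' four sensor p-values.
#'
#' @param specA,specB `spectral_set`s for the two conditions (both must span
#'   all four sensors).
#' @param bands named list of [band_definition()]s (default: broad, beta,
#'   alpha).
#' @param var_equal pooled-variance t-tests.
#' @param contrast label stored with the result (e.g. `"BL_vs_FP"`).
#' @return object of class `band_test_result`: `tests` (data.frame: band,
#'   sensor, p, effect_db, n_a, n_b) and `summary` (band, avg_p).
#' @export
contrast_bands <- function(specA, specB, bands = default_bands(),
                           var_equal = FALSE, contrast = "A_vs_B") {
  for (s in list(specA, specB)) {
    miss <- setdiff(CHANNELS, unique(s$labels$sensor))
    if (length(miss)) {
      validation_error(paste("spectral set missing sensors:", paste(miss, collapse = ", ")))
    }
  }
  rows <- list()
  for (bn in names(bands)) {
    bpA <- band_power(specA, bands[[bn]])
    bpB <- band_power(specB, bands[[bn]])
    for (ch in CHANNELS) {
      a <- bpA[specA$labels$sensor == ch]
      b <- bpB[specB$labels$sensor == ch]
      tt <- band_ttest(a, b, var_equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        band = bn, sensor = ch, p = tt$p, effect_db = tt$effect,
        n_a = tt$n[1], n_b = tt$n[2], stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(bands), function(bn) {
    data.frame(band = bn, avg_p = mean(tests$p[tests$band == bn]),
               stringsAsFactors = FALSE)
  }))
  structure(list(contrast = contrast, tests = tests, summary = summary),
            class = "band_test_result")
}

#' @export
print.band_test_result <- function(x, ...) {
  cat(sprintf("Band contrast %s\n", x$contrast))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-6s avg p = %.4f\n", x$summary$band[i], x$summary$avg_p[i]))
  }
  invisible(x)
}

#' Random non-favorite-painting control selection
#'
#' For each subject, selects uniformly at random one viewed piece different
#' from the favorite; its epochs form the NFP condition. Reproducible under
#' `seed`; subjects whose epochs cover only their favorite piece are dropped
#' with a warning.
#'
#' @param labels epoch label data.frame with `subject` and `condition`
#'   (piece labels `P1`-`P8`).
#' @param favorites named vector/list: subject -> favorite piece label.
#' @param seed integer seed.
#' @return data.frame `subject`, `nfp_piece`; attribute `"epoch_rows"` holds
#'   the row indices of `labels` belonging to the selected pieces.
#' @export
nfp_control <- function(labels, favorites, seed) {
  set.seed(as.integer(seed))
  subjects <- sort(unique(labels$subject))
  out <- list()
  for (s in subjects) {
    fav <- favorites[[s]]
    pieces <- setdiff(sort(unique(labels$condition[labels$subject == s & labels$condition %in% PIECES])), fav)
    if (length(pieces) == 0L) {
      warning(sprintf("subject %s has epochs only for the favorite piece; excluded from NFP", s))
      next
    }
    pick <- if (length(pieces) == 1L) pieces else sample(pieces, 1)
    out[[length(out) + 1L]] <- data.frame(subject = s, nfp_piece = pick,
                                          stringsAsFactors = FALSE)
  }
  sel <- if (length(out)) do.call(rbind, out) else
    data.frame(subject = character(0), nfp_piece = character(0))
  rows <- integer(0)
  for (i in seq_len(nrow(sel))) {
    rows <- c(rows, which(labels$subject == sel$subject[i] &
                            labels$condition == sel$nfp_piece[i]))
  }
  attr(sel, "epoch_rows") <- rows
  sel
}

#' Per-frequency-bin mean and 90%-of-data envelope
#'
#' Empirical per-bin mean and percentile envelope (default 5th/95th, i.e.
#' "90% of data") across a set of spectral vectors.
#'
#' @param x `spectral_set` or numeric matrix (epochs x bins).
#' @param level central fraction of data the envelope covers.
#' @param min_n minimum number of vectors required.
#' @return object of class `ci_curve`: `mean`, `lower`, `upper`, `freqs`.
#' @export
ci_curve <- function(x, level = 0.90, min_n = 10L) {
  vals <- if (inherits(x, "spectral_set")) x$values else as.matrix(x)
  freqs <- if (inherits(x, "spectral_set")) x$freqs else seq_len(ncol(vals))
  if (nrow(vals) < min_n) {
    validation_error(sprintf("need at least %d vectors for an envelope", min_n))
  }
  tail <- (1 - level) / 2
  structure(list(
    mean = colMeans(vals),
    lower = apply(vals, 2, quantile, probs = tail, names = FALSE),
    upper = apply(vals, 2, quantile, probs = 1 - tail, names = FALSE),
    freqs = freqs, level = level), class = "ci_curve")
}

#' Per-bin non-overlap indicator between two envelope curves
#' @param a,b `ci_curve`s on the same grid.
#' @return logical vector: TRUE where the envelopes do not overlap.
#' @export
ci_nonoverlap <- function(a, b) {
  stopifnot(inherits(a, "ci_curve"), inherits(b, "ci_curve"))
  a$lower > b$upper | b$lower > a$upper
}
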