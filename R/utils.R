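# Internal helpers shared across modules.

# Typed error for file parsing; `line` is 1-based and includes the header.
parse_error <- function(msg, path = NULL, line = NULL) {
  loc <- c(
    if (!is.null(path)) sprintf("file '%s'", path),
    if (!is.null(line)) sprintf("line %d", line)
  )
  full <- if (length(loc)) paste0(msg, " (", paste(loc, collapse = ", "), ")") else msg
  stop(errorCondition(full, class = c("mobispec_parse_error", "mobispec_error")))
}

validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("mobispec_validation_error", "mobispec_error")))
}

stopifnot_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    validation_error(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) {
    validation_error(sprintf("'%s' must be strictly positive", name))
  }
  invisible(x)
}

# Deterministic per-subject seed below 2^31, derived from a base seed and the
# subject identifier.
subject_seed <- function(seed, subject) {
  h <- sum(utf8ToInt(as.character(subject)) * seq_along(utf8ToInt(as.character(subject))))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483647)
}

# Expand a logical vector of flags by +/- `margin` positions.
dilate_flags <- function(flags, margin) {
  n <- length(flags)
  idx <- which(flags)
  if (length(idx) == 0L || margin <= 0) return(flags)
  delta <- integer(n + 1L)
  starts <- pmax(idx - margin, 1L)
  ends <- pmin(idx + margin, n)
  for (i in seq_along(starts)) {
    delta[starts[i]] <- delta[starts[i]] + 1L
    delta[ends[i] + 1L] <- delta[ends[i] + 1L] - 1L
  }
  cumsum(delta[seq_len(n)]) > 0L
}

# Runs of TRUE in a logical vector as a data.frame of [start, end] indices.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
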