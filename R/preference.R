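# Demographics and aesthetic-preference statistics: empirical preference
# distributions with top-choice margins, distribution-shift tests between
# cohorts, and appreciation-time summaries from the event log.

#' Empirical aesthetic-preference distribution
#'
#' @param questionnaire questionnaire data.frame (see [read_questionnaire()]).
#' @param subset optional logical vector or predicate function selecting the
#'   subject rows (e.g. a gender x age cohort).
#' @param label descriptive group label.
#' @return object of class `preference_distribution`: `counts` and `probs`
#'   per piece 1-8, `top` piece, `margin` = P(top) - P(runner-up), `n`.
#' @export
preference_distribution <- function(questionnaire, subset = NULL, label = "all") {
  q <- questionnaire
  if (!is.null(subset)) {
    keep <- if (is.function(subset)) subset(q) else subset
    q <- q[keep, , drop = FALSE]
  }
  if (nrow(q) == 0L) validation_error("no subjects pass the filter")
  counts <- tabulate(q$favorite_piece, nbins = 8)
  names(counts) <- PIECES
  probs <- counts / sum(counts)
  ord <- order(probs, decreasing = TRUE)
  margin <- probs[ord[1]] - probs[ord[2]]
  structure(list(label = label, counts = counts, probs = probs,
                 top = ord[1], margin = unname(margin), n = nrow(q)),
            class = "preference_distribution")
}

#' @export
print.preference_distribution <- function(x, ...) {
  cat(sprintf("Preference distribution [%s], n=%d: top piece %d (P=%.3f, margin %.4f)\n",
              x$label, x$n, x$top, x$probs[x$top], x$margin))
  invisible(x)
}

# chi-square statistic of a 2 x m count table against margin-derived
# expectations; zero-total columns are dropped.
table_chisq <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Exact conditional test: enumerate all 2 x m tables with the observed
# margins, weight by the multivariate hypergeometric probability, and sum the
# probability of tables whose chi-square statistic is at least the observed.
exact_shift_p <- function(tab) {
  cs <- colSums(tab)
  keep <- cs > 0
  tab <- tab[, keep, drop = FALSE]
  cs <- cs[keep]
  r1 <- sum(tab[1, ])
  n <- sum(tab)
  obs <- table_chisq(tab)
  m <- length(cs)
  denom <- lchoose(n, r1)
  p <- 0
  recurse <- function(j, remaining, row1, logw) {
    if (j > m) {
      if (remaining == 0L) {
        t2 <- rbind(row1, cs - row1)
        if (table_chisq(t2) >= obs - 1e-9) p <<- p + exp(logw - denom)
      }
      return(invisible())
    }
    rest_cap <- if (j < m) sum(cs[(j + 1):m]) else 0L
    lo <- max(0L, remaining - rest_cap)
    hi <- min(cs[j], remaining)
    for (x in lo:hi) {
      recurse(j + 1L, remaining - x, c(row1, x), logw + lchoose(cs[j], x))
    }
  }
  recurse(1L, r1, integer(0), 0)
  min(p, 1)
}

#' Test for a shift between two preference distributions
#'
#' Default: a seeded Monte-Carlo permutation test of the 2 x 8 count table --
#' group labels are permuted with group sizes fixed (equivalently, tables are
#' drawn with both margins fixed) and the chi-square statistic is compared to
#' its permutation distribution; `p = (1 + #extreme) / (B + 1)`. For small
#' problems (total n <= 20, or `method = "exact"`) the conditional null is
#' enumerated exactly.
#'
#' @param distA,distB [preference_distribution()]s on the same piece support.
#' @param method `"auto"`, `"permutation"`, or `"exact"`.
#' @param n_perm Monte-Carlo permutation count.
#' @param seed integer seed for the permutation draw.
#' @return list: `p`, `method`, `statistic` (observed chi-square), `n`.
#' @export
distribution_shift_test <- function(distA, distB, method = c("auto", "permutation", "exact"),
                                    n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  tab <- rbind(distA$counts, distB$counts)
  if (sum(tab) == 0) validation_error("all counts are zero")
  n <- sum(tab)
  if (method == "auto") method <- if (n <= 20) "exact" else "permutation"
  stat <- table_chisq(tab)
  if (method == "exact") {
    p <- exact_shift_p(tab)
  } else {
    set.seed(as.integer(seed))
    keep <- colSums(tab) > 0
    sim <- suppressWarnings(
      chisq.test(tab[, keep, drop = FALSE], simulate.p.value = TRUE, B = n_perm))
    p <- unname(sim$p.value)
  }
  list(p = p, method = method, statistic = stat, n = n)
}

#' Disjoint cohort split for preference comparison
#'
#' Compares a cohort against the *rest* of the population rather than against
#' the full population the cohort is part of (`mode = "literal"` gives the
#' overlapping comparison).
#'
#' @param questionnaire questionnaire table.
#' @param cohort logical vector selecting cohort rows.
#' @param mode `"disjoint"` or `"literal"`.
#' @return list of two [preference_distribution()]s (`cohort`, `reference`).
#' @export
cohort_split <- function(questionnaire, cohort, mode = c("disjoint", "literal")) {
  mode <- match.arg(mode)
  ref <- if (mode == "disjoint") !cohort else rep(TRUE, nrow(questionnaire))
  list(cohort = preference_distribution(questionnaire, cohort, label = "cohort"),
       reference = preference_distribution(questionnaire, ref,
                                           label = if (mode == "disjoint") "non-cohort" else "population"))
}

#' Appreciation-time summary from the event log
#'
#' Viewing durations (minutes) per (subject, piece), summarized per piece and
#' per tour group with mean and sample variance.
#'
#' @param log an [event_log()].
#' @return list: `durations` (subject, group, piece, minutes), `per_piece`
#'   and `per_group` data.frames with n, mean and variance.
#' @export
appreciation_summary <- function(log) {
  v <- log[log$condition %in% PIECES, , drop = FALSE]
  if (nrow(v) == 0L) validation_error("event log has no viewing intervals")
  durations <- data.frame(subject = v$subject, group = v$group,
                          piece = v$condition,
                          minutes = (v$end_s - v$start_s) / 60,
                          stringsAsFactors = FALSE)
  summarize_by <- function(key) {
    parts <- split(durations$minutes, durations[[key]])
    data.frame(key = names(parts),
               n = vapply(parts, length, integer(1)),
               mean = vapply(parts, mean, numeric(1)),
               variance = vapply(parts, function(x) if (length(x) > 1) var(x) else 0,
                                 numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  pp <- summarize_by("piece"); names(pp)[1] <- "piece"
  pg <- summarize_by("group"); names(pg)[1] <- "group"
  list(durations = durations, per_piece = pp, per_group = pg)
}
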