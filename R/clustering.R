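# Ward hierarchical clustering of spectral vectors, Calinski-Harabasz model
# selection, and the epoch-to-variable correspondence / separability
# analysis.

#' Standardize matrix columns to mean 0, sd 1 (sample convention)
#'
#' @param X numeric matrix with at least two rows.
#' @param drop_constant drop zero-variance columns instead of erroring.
#' @return standardized matrix (attribute `dropped` lists removed columns).
#' @export
standardize_columns <- function(X, drop_constant = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) validation_error("need at least 2 rows to standardize")
  sds <- apply(X, 2, sd)
  const <- sds < .Machine$double.eps^0.5
  if (any(const)) {
    if (!drop_constant) {
      validation_error(sprintf("constant column(s): %s",
                               paste(which(const), collapse = ", ")))
    }
    X <- X[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  out <- scale(X, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped") <- which(const)
  out
}

#' Ward hierarchical clustering cut to K clusters
#'
#' Agglomerative Ward linkage (minimum increase in within-cluster sum of
#' squares, Euclidean distances; `hclust(method = "ward.D2")`) cut to exactly
#' `K` clusters. Deterministic for a given matrix.
#'
#' @param X n x d numeric matrix (standardize first for the spectral
#'   pipeline).
#' @param K number of clusters, `1 <= K <= n`.
#' @param linkage precomputed `hclust` tree to reuse across cuts.
#' @return object of class `cluster_model`: `X`, `linkage`, `labels`, `K`,
#'   `sizes`, `centroids`, `grand_mean`.
#' @export
ward_cluster <- function(X, K, linkage = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (K < 1 || K > n) validation_error(sprintf("K must be in 1..%d", n))
  if (is.null(linkage)) linkage <- hclust(dist(X), method = "ward.D2")
  labels <- if (K == n) seq_len(n) else cutree(linkage, k = K)
  sizes <- tabulate(labels, nbins = K)
  centroids <- rowsum(X, labels) / sizes
  structure(list(X = X, linkage = linkage, labels = labels, K = as.integer(K),
                 sizes = sizes, centroids = centroids,
                 grand_mean = colMeans(X)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Ward cluster model: n=%d, K=%d, sizes: %s\n",
              nrow(x$X), x$K, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Calinski-Harabasz index of a partition
#'
#' `CH = (B / (K - 1)) / (W / (n - K))` where `W` is the within-cluster sum
#' of squared distances to cluster centroids and `B` the size-weighted sum of
#' squared centroid-to-grand-mean distances. `literal = TRUE` evaluates the
#' within term against the grand mean instead of the cluster centroids
#' (audit mode for the variance-ratio reading; not the standard index).
#'
#' @param X n x d matrix.
#' @param labels integer cluster assignment per row.
#' @param literal use the grand mean in the within term.
#' @return the index value; `Inf` when `W` is exactly zero.
#' @export
ch_index <- function(X, labels, literal = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  ks <- sort(unique(labels))
  K <- length(ks)
  if (K < 2 || K >= n) {
    validation_error("CH index requires 2 <= K <= n - 1")
  }
  gm <- colMeans(X)
  W <- 0; B <- 0
  for (k in ks) {
    rows <- which(labels == k)
    Xi <- X[rows, , drop = FALSE]
    ck <- colMeans(Xi)
    ref <- if (literal) gm else ck
    W <- W + sum(sweep(Xi, 2, ref)^2)
    B <- B + length(rows) * sum((ck - gm)^2)
  }
  if (W == 0) return(Inf)
  (B / (K - 1)) / (W / (n - K))
}

#' Select the number of clusters by the CH index over Ward cuts
#'
#' Evaluates the CH index on Ward-tree cuts for `k = 2 .. k_max` and returns
#' the smallest argmax. A flatness diagnostic (max/median ratio of the curve)
#' is attached: values near 1 signal no dominant interior peak, i.e. weak
#' evidence for any particular k.
#'
#' @param X n x d matrix.
#' @param k_max largest k to evaluate (default 15, truncated to `n - 1`).
#' @param literal passed to [ch_index()].
#' @return list of class `ch_curve`: `k` (selected), `curve` (data.frame with
#'   k, ch), `flatness`, `linkage`.
#' @export
select_k_ch <- function(X, k_max = 15, literal = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k_max < 2) validation_error("'k_max' must be >= 2")
  k_max <- min(k_max, n - 1L)
  linkage <- hclust(dist(X), method = "ward.D2")
  ks <- 2:k_max
  ch <- vapply(ks, function(k) {
    ch_index(X, cutree(linkage, k = k), literal = literal)
  }, numeric(1))
  best <- ks[which.max(ch)] # which.max: first (smallest k) on ties
  structure(list(k = best, curve = data.frame(k = ks, ch = ch),
                 flatness = max(ch) / stats::median(ch), linkage = linkage),
            class = "ch_curve")
}

#' @export
print.ch_curve <- function(x, ...) {
  cat(sprintf("CH curve over k=%d..%d: k* = %d (flatness %.2f)\n",
              min(x$curve$k), max(x$curve$k), x$k, x$flatness))
  invisible(x)
}

#' Number of clusters by the variables-plus-one strategy
#' @param variables character vector of analysis variables.
#' @return `length(variables) + 1`.
#' @export
select_k_variables <- function(variables) {
  if (length(variables) == 0L) validation_error("need at least one variable")
  length(variables) + 1L
}

#' Standard per-epoch variable indicators
#'
#' Builds the analysis variables of the correspondence tables: gender (male,
#' female), sensor (TP9, AF7, AF8, TP10) and, when requested, explanation
#' (explained, not_explained).
#'
#' @param labels epoch label data.frame with `gender`, `sensor` and
#'   optionally `explained` columns.
#' @param include_explained add the explained/not_explained pair.
#' @return named list of logical vectors, one per variable.
#' @export
epoch_variables <- function(labels, include_explained = FALSE) {
  vars <- list(male = labels$gender == "male",
               female = labels$gender == "female")
  for (ch in CHANNELS) vars[[ch]] <- labels$sensor == ch
  if (include_explained) {
    vars$explained <- as.logical(labels$explained)
    vars$not_explained <- !as.logical(labels$explained)
  }
  vars
}

#' Epoch-to-variable correspondence table
#'
#' For each analysis variable, the percentage of that variable's epochs
#' falling in each cluster (rows sum to 100). Cells above the uniform
#' reference `100 / K` are marked; a cluster that is above average for every
#' variable and holds the most epochs is flagged as the noise cluster.
#'
#' @param model a `cluster_model` (or an integer label vector).
#' @param variables named list of logical vectors as from [epoch_variables()].
#' @return object of class `correspondence_table`: `percent` (V x K matrix),
#'   `above_average` (logical matrix), `average` (= 100/K), `noise_cluster`
#'   (integer or NA).
#' @export
correspondence_table <- function(model, variables) {
  labels <- if (inherits(model, "cluster_model")) model$labels else model
  K <- length(unique(labels))
  ks <- sort(unique(labels))
  V <- length(variables)
  percent <- matrix(NA_real_, V, K, dimnames = list(names(variables), paste0("K", ks)))
  for (v in seq_len(V)) {
    sel <- variables[[v]]
    tot <- sum(sel)
    if (tot == 0L) {
      warning(sprintf("variable '%s' has zero epochs; row is NaN", names(variables)[v]))
      percent[v, ] <- NaN
      next
    }
    percent[v, ] <- 100 * tabulate(match(labels[sel], ks), nbins = K) / tot
  }
  avg <- 100 / K
  above <- percent > avg
  noise <- NA_integer_
  all_above <- which(apply(above, 2, function(col) all(col[!is.na(col)])))
  if (length(all_above)) {
    sizes <- tabulate(match(labels, ks), nbins = K)
    noise <- all_above[which.max(sizes[all_above])]
  }
  structure(list(percent = percent, above_average = above, average = avg,
                 noise_cluster = noise, cluster_ids = ks),
            class = "correspondence_table")
}

#' @export
print.correspondence_table <- function(x, ...) {
  cat(sprintf("Correspondence table (%% of each variable's epochs per cluster; average %.1f%%)\n",
              x$average))
  print(round(x$percent, 1))
  if (!is.na(x$noise_cluster)) {
    cat(sprintf("noise cluster: K%d\n", x$cluster_ids[x$noise_cluster]))
  }
  invisible(x)
}

#' Variable separability report from a correspondence table
#'
#' Two variables are *co-clustered* when their above-average cluster sets
#' (noise cluster excluded) intersect, i.e. some cluster concentrates epochs
#' of both and so fails to isolate one variable from the other; a pair is
#' *separable* when the two sets are disjoint.
#'
#' @param table a [correspondence_table()].
#' @return data.frame with one row per variable pair: `var_a`, `var_b`,
#'   `co_clustered`, `separable`.
#' @export
separability_report <- function(table) {
  stopifnot(inherits(table, "correspondence_table"))
  above <- table$above_average
  if (!is.na(table$noise_cluster)) above <- above[, -table$noise_cluster, drop = FALSE]
  vars <- rownames(above)
  pairs <- utils::combn(vars, 2)
  res <- data.frame(var_a = pairs[1, ], var_b = pairs[2, ],
                    co_clustered = NA, separable = NA)
  for (i in seq_len(ncol(pairs))) {
    a <- above[pairs[1, i], ]; b <- above[pairs[2, i], ]
    a[is.na(a)] <- FALSE; b[is.na(b)] <- FALSE
    res$co_clustered[i] <- any(a & b)
    res$separable[i] <- !any(a & b)
  }
  res
}
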