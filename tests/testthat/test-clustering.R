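test_that("column standardization follows the sample-sd convention", {
  X <- cbind(c(0, 2), c(1, 3))
  Z <- standardize_columns(X)
  expect_equal(Z[, 1], c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(1)
  R <- matrix(rnorm(200), 20, 10)
  Z <- standardize_columns(R)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(apply(Z, 2, sd), rep(1, 10), tolerance = 1e-12)
  expect_equal(unclass(standardize_columns(Z)), unclass(Z),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(standardize_columns(cbind(c(1, 1), c(0, 1))), "constant column")
  Zd <- standardize_columns(cbind(c(1, 1), c(0, 1)), drop_constant = TRUE)
  expect_equal(ncol(Zd), 1)
})

test_that("Ward cuts behave at the degenerate K extremes", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  m1 <- ward_cluster(X, 1)
  expect_equal(length(unique(m1$labels)), 1)
  w_total <- sum(sweep(X, 2, colMeans(X))^2)
  within <- function(m) {
    sum(vapply(seq_len(m$K), function(k) {
      rows <- m$labels == k
      sum(sweep(X[rows, , drop = FALSE], 2, m$centroids[k, ])^2)
    }, numeric(1)))
  }
  expect_equal(within(m1), w_total)
  mn <- ward_cluster(X, 10)
  expect_equal(within(mn), 0)
  expect_error(ward_cluster(X, 11), "K must be in")
})

test_that("well-separated blobs are recovered exactly at K = 2", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, sd = 0.1), 20, 2),
             matrix(rnorm(40, mean = 10, sd = 0.1), 20, 2))
  truth <- rep(1:2, each = 20)
  m <- ward_cluster(X, 2)
  agree <- max(mean(m$labels == truth), mean(m$labels == 3 - truth))
  expect_equal(agree, 1)
})

test_that("CH index matches hand and brute-force evaluation", {
  X <- matrix(c(0, 1, 5, 6), ncol = 1)
  labels <- c(1, 1, 2, 2)
  expect_equal(ch_index(X, labels), 50)

  # zero within-cluster scatter: +Inf sentinel
  Xd <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  expect_equal(ch_index(Xd, c(1, 1, 2, 2)), Inf)

  expect_error(ch_index(X, rep(1, 4)), "2 <= K")
  expect_error(ch_index(X, 1:4), "2 <= K")

  set.seed(4)
  for (rep in 1:10) {
    n <- sample(6:50, 1)
    d <- sample(1:10, 1)
    K <- sample(2:4, 1)
    Xr <- matrix(rnorm(n * d), n, d)
    lab <- sample(rep(1:K, length.out = n))
    expect_equal(ch_index(Xr, lab), brute_ch(Xr, lab), tolerance = 1e-10)
  }
})

test_that("CH index is invariant under translation and rotation", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  lab <- sample(1:3, 20, replace = TRUE)
  base <- ch_index(X, lab)
  expect_equal(ch_index(X + 100, lab), base, tolerance = 1e-9)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(ch_index(X %*% Q, lab), base, tolerance = 1e-9)
})

test_that("literal variance-ratio mode uses the grand mean in the within term", {
  X <- matrix(c(0, 1, 5, 6), ncol = 1)
  lab <- c(1, 1, 2, 2)
  # W_literal = sum (x - 3)^2 = 9+4+4+9 = 26 -> CH = 25 / 13
  expect_equal(ch_index(X, lab, literal = TRUE), (25 / 1) / (26 / 2))
})

test_that("CH selection finds planted cluster counts", {
  two <- make_two_template(n_per = 30, distance = 8, seed = 6)
  sel <- select_k_ch(standardize_columns(two$X), k_max = 8)
  expect_equal(sel$k, 2)

  set.seed(7)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  X3 <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(30, sd = 0.5), 15, 2, byrow = TRUE) + rep(centers[k, ], each = 15)))
  sel3 <- select_k_ch(X3, k_max = 6)
  expect_equal(sel3$k, 3)

  # single isotropic Gaussian: curve is flat, diagnostic near 1
  set.seed(8)
  X1 <- matrix(rnorm(300), 75, 4)
  sel1 <- select_k_ch(X1, k_max = 8)
  expect_true(is.numeric(sel1$flatness))
  expect_lt(sel1$flatness, sel$flatness) # far flatter than a real 2-cluster curve
})

test_that("within-cluster sum of squares is non-increasing along tree cuts", {
  set.seed(9)
  X <- matrix(rnorm(200), 50, 4)
  link <- hclust(dist(X), method = "ward.D2")
  wss <- vapply(1:10, function(k) {
    lab <- cutree(link, k)
    sum(vapply(unique(lab), function(g) {
      rows <- lab == g
      sum(sweep(X[rows, , drop = FALSE], 2,
                colMeans(X[rows, , drop = FALSE]))^2)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(wss) <= 1e-9))
})

test_that("variables-plus-one strategy matches the two analysis sets", {
  expect_equal(select_k_variables(c("male", "female", "TP9", "AF7", "AF8", "TP10")), 7)
  expect_equal(select_k_variables(c("male", "female", "TP9", "AF7", "AF8", "TP10",
                                    "explained", "not_explained")), 9)
  expect_equal(select_k_variables("x"), 2)
  expect_error(select_k_variables(character(0)), "at least one")
})

test_that("correspondence table percentages and markers are exact", {
  labels <- c(2, 2, 2, 2, 1, 3, 1, 2, 3, 3, 1, 2)
  vars <- list(a = rep(c(TRUE, FALSE), each = 6),
               b = rep(c(FALSE, TRUE), each = 6))
  tab <- correspondence_table(labels, vars)
  # a: clusters (1,2,3) = (1,4,1)/6 ; b: (2,2,2)/6
  expect_equal(unname(tab$percent["a", ]), 100 * c(1, 4, 1) / 6)
  expect_equal(unname(tab$percent["b", ]), 100 * c(2, 2, 2) / 6)
  expect_equal(rowSums(tab$percent), c(a = 100, b = 100), tolerance = 1e-9)
  expect_equal(unname(tab$above_average["a", ]), c(FALSE, TRUE, FALSE))
  expect_false(any(tab$above_average["b", ])) # exactly uniform: never above

  one <- correspondence_table(c(2, 2, 2, 1, 3), list(v = c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  expect_equal(unname(one$percent["v", ]), c(0, 100, 0))

  expect_warning(tab0 <- correspondence_table(labels, list(z = rep(FALSE, 12))),
                 "zero epochs")
  expect_true(all(is.nan(tab0$percent["z", ])))
})

test_that("separability report reads the above-average cluster sets", {
  labels <- rep(1:2, each = 10)
  vars <- list(p = rep(c(TRUE, FALSE), each = 10),
               q = rep(c(TRUE, FALSE), each = 10),
               r = rep(c(FALSE, TRUE), each = 10))
  rep_ <- separability_report(correspondence_table(labels, vars))
  pq <- rep_[rep_$var_a == "p" & rep_$var_b == "q", ]
  pr <- rep_[rep_$var_a == "p" & rep_$var_b == "r", ]
  expect_true(pq$co_clustered)
  expect_false(pq$separable)
  expect_false(pr$co_clustered)
  expect_true(pr$separable)
})

test_that("planted sensor structure separates, absent effects do not", {
  # frontal vs posterior templates; explained split orthogonal to spectra
  set.seed(10)
  n <- 160
  sensor <- sample(channels, n, replace = TRUE)
  explained <- sample(c(TRUE, FALSE), n, replace = TRUE)
  gender <- sample(c("male", "female"), n, replace = TRUE)
  X <- matrix(rnorm(n * 60, sd = 1), n, 60)
  X[sensor %in% c("TP9", "TP10"), ] <- X[sensor %in% c("TP9", "TP10"), ] + 3
  lab_df <- data.frame(sensor = sensor, gender = gender, explained = explained)
  vars <- epoch_variables(lab_df, include_explained = TRUE)
  model <- ward_cluster(standardize_columns(X), 9)
  tab <- correspondence_table(model, vars)
  rep_ <- separability_report(tab)
  get <- function(a, b) rep_[(rep_$var_a == a & rep_$var_b == b) |
                               (rep_$var_a == b & rep_$var_b == a), ]
  expect_true(get("AF7", "AF8")$co_clustered)
  expect_true(get("TP9", "TP10")$co_clustered)
  expect_false(get("explained", "not_explained")$separable)
  expect_true(get("AF7", "TP9")$separable)
})
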