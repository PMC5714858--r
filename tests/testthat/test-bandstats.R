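test_that("band t-test matches the textbook Welch formula", {
  set.seed(1)
  a <- rnorm(50, mean = 1)
  b <- rnorm(50)
  res <- band_ttest(a, b)
  # independent Welch oracle
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(res$t, tstat, tolerance = 1e-10)
  expect_equal(res$p, p, tolerance = 1e-10)
  expect_equal(res$effect, mean(a) - mean(b))
})

test_that("degenerate t-test inputs follow the stated conventions", {
  a <- rnorm(10)
  same <- band_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(band_ttest(rep(2, 5), rep(2, 5))$p, 1)
  expect_equal(band_ttest(rep(2, 5), rep(3, 5))$p, 0)
  expect_error(band_ttest(1, rnorm(5)), "at least 2")
})

test_that("planted -2 dB beta suppression is detected with high power", {
  rejections <- c(AF7 = 0, AF8 = 0)
  n_runs <- 20
  for (r in seq_len(n_runs)) {
    cfg <- tiny_generator(seed = 400 + r, n_subjects = 1, artifact_rate = 0,
                          baseline_duration = 60,
                          viewing_duration_range = c(55, 60))
    st <- generate_study(cfg)
    ep <- extract_epochs(st$recordings$S001, NULL, st$log)
    sp <- spectral_dataset(ep, baseline = "subject")
    bp <- band_power(sp, default_bands()$beta)
    fav <- paste0("P", st$questionnaire$favorite_piece[1])
    for (ch in c("AF7", "AF8")) {
      a <- bp[sp$labels$sensor == ch & sp$labels$condition == "BL"]
      b <- bp[sp$labels$sensor == ch & sp$labels$condition == fav]
      if (band_ttest(a, b)$p < 0.05) rejections[ch] <- rejections[ch] + 1
    }
  }
  expect_gte(min(rejections) / n_runs, 0.9)
})

test_that("contrast_bands reports per-sensor tests and exact average p", {
  cfg <- tiny_generator(seed = 41, n_subjects = 1, artifact_rate = 0)
  st <- generate_study(cfg)
  ep <- extract_epochs(st$recordings$S001, NULL, st$log)
  sp <- spectral_dataset(ep, baseline = "subject")
  bl <- sp$labels$condition == "BL"
  p1 <- sp$labels$condition == "P1"
  specA <- mobispec:::subset_spectra(sp, which(bl))
  specB <- mobispec:::subset_spectra(sp, which(p1))
  res <- contrast_bands(specA, specB)
  expect_equal(nrow(res$tests), 12) # 3 bands x 4 sensors
  for (bn in res$summary$band) {
    expect_equal(res$summary$avg_p[res$summary$band == bn],
                 mean(res$tests$p[res$tests$band == bn]), tolerance = 1e-12)
  }
  ident <- contrast_bands(specA, specA)
  expect_true(all(ident$tests$p == 1))
  expect_true(all(ident$tests$effect_db == 0))
})

test_that("NFP control selects uniformly among non-favorite pieces", {
  labels <- data.frame(subject = "S1",
                       condition = rep(c("P1", "P2", "P3"), each = 4))
  sel <- nfp_control(labels, list(S1 = "P3"), seed = 1)
  expect_true(sel$nfp_piece %in% c("P1", "P2"))
  expect_identical(nfp_control(labels, list(S1 = "P3"), seed = 1), sel)
  expect_length(attr(sel, "epoch_rows"), 4)

  # only the favorite viewed: excluded with a warning
  solo <- data.frame(subject = "S2", condition = rep("P5", 3))
  expect_warning(out <- nfp_control(solo, list(S2 = "P5"), seed = 1),
                 "only for the favorite")
  expect_equal(nrow(out), 0)

  # one candidate: chosen with probability 1
  one <- data.frame(subject = "S3", condition = rep(c("P1", "P2"), each = 2))
  expect_equal(nfp_control(one, list(S3 = "P1"), seed = 9)$nfp_piece, "P2")

  # marginal uniformity over 7 candidates across 7000 seeded draws
  all8 <- data.frame(subject = "S4", condition = paste0("P", 1:8))
  picks <- vapply(1:7000, function(s) {
    nfp_control(all8, list(S4 = "P8"), seed = s)$nfp_piece
  }, character(1))
  counts <- table(factor(picks, levels = paste0("P", 1:7)))
  sd_bound <- 3 * sqrt(7000 * (1 / 7) * (6 / 7))
  expect_true(all(abs(counts - 1000) <= sd_bound))
})

test_that("envelope curves match order-statistics and flag planted bands", {
  same <- matrix(5, 20, 10)
  cv <- ci_curve(same)
  expect_equal(cv$lower, cv$upper)
  expect_equal(cv$mean, rep(5, 10))

  set.seed(2)
  X <- matrix(rnorm(600), 30, 20)
  cv <- ci_curve(X)
  oracle <- apply(X, 2, function(col) quantile(col, c(0.05, 0.95), names = FALSE))
  expect_equal(cv$lower, oracle[1, ])
  expect_equal(cv$upper, oracle[2, ])
  expect_true(all(cv$lower <= cv$mean & cv$mean <= cv$upper))
  expect_error(ci_curve(X[1:5, ]), "at least 10")

  # large planted shift confined to beta bins
  freqs <- (1:60) * 220 / 256
  beta_bins <- freqs >= 15 & freqs <= 25
  A <- matrix(rnorm(100 * 60, sd = 0.3), 100, 60)
  B <- matrix(rnorm(100 * 60, sd = 0.3), 100, 60)
  B[, beta_bins] <- B[, beta_bins] - 4
  flag <- ci_nonoverlap(ci_curve(A), ci_curve(B))
  expect_true(all(flag[beta_bins]))
  expect_false(any(flag[!beta_bins]))
})

test_that("detection power grows with effect size and sample size", {
  rate <- function(effect, n, reps = 200) {
    mean(vapply(seq_len(reps), function(r) {
      set.seed(r * 1000 + n + round(100 * effect))
      band_ttest(rnorm(n, mean = effect), rnorm(n))$p < 0.05
    }, logical(1)))
  }
  by_effect <- c(rate(0, 30), rate(0.5, 30), rate(1.5, 30))
  expect_true(all(diff(by_effect) > 0))
  by_n <- c(rate(0.5, 10), rate(0.5, 40), rate(0.5, 160))
  expect_true(all(diff(by_n) > 0))
})
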