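# End-to-end orchestration: simulate (or load) -> screen -> filter ->
# artifact mask -> epochs -> spectra -> clustering/correspondence -> band
# contrasts -> preference statistics, under one seeded configuration.

#' Pipeline configuration
#'
#' All stage parameters in one validated list. Unknown keys are rejected.
#'
#' @param generator a [generator_config()] used when no `input_dir` is given.
#' @param input_dir optional directory with a written study
#'   ([write_study()]); overrides the generator.
#' @param out_dir optional output directory for result tables and the
#'   resolved configuration.
#' @param low,high band-pass edges (Hz).
#' @param accel_thresh,amp_thresh,axis_rule,dilate_s artifact screen
#'   parameters (see [detect_artifacts()]).
#' @param window,overlap epoching parameters (see [extract_epochs()]).
#' @param nw,n_tapers multitaper parameters.
#' @param baseline baseline-correction mode (see [spectral_dataset()]).
#' @param k_max CH search range upper bound.
#' @param max_cluster_epochs cap on epochs entering a clustering (seeded
#'   subsample; the O(n^2) distance matrix is the constraint).
#' @param var_equal pooled-variance t-tests instead of Welch.
#' @param alpha significance level used in the report's flags.
#' @param seed master seed for NFP selection and subsampling.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...,
                            generator = generator_config(),
                            input_dir = NULL, out_dir = NULL,
                            low = 1, high = 50,
                            accel_thresh = 2, amp_thresh = 40,
                            axis_rule = "all", dilate_s = 0.5,
                            window = 256L, overlap = 0,
                            nw = 4, n_tapers = 7,
                            baseline = "subject",
                            k_max = 15, max_cluster_epochs = 1500L,
                            var_equal = FALSE, alpha = 0.05,
                            seed = 1L) {
  extra <- names(list(...))
  if (length(extra)) {
    validation_error(paste("unknown config keys:", paste(extra, collapse = ", ")))
  }
  cfg <- as.list(environment())
  cfg$extra <- NULL
  class(cfg) <- "pipeline_config"
  cfg
}

subset_spectra <- function(spec, rows) {
  structure(list(values = spec$values[rows, , drop = FALSE],
                 freqs = spec$freqs,
                 labels = spec$labels[rows, , drop = FALSE],
                 corrected = spec$corrected, bank = spec$bank),
            class = "spectral_set")
}

seeded_subsample <- function(n, size, seed) {
  if (n <= size) return(seq_len(n))
  set.seed(as.integer(seed))
  sort(sample.int(n, size))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, subject screening, band-pass filtering, the
#' multimodal artifact screen, epoch extraction, multitaper spectral vectors
#' with baseline correction, Ward/CH clustering with correspondence and
#' separability analysis (baseline and favorite-piece sets), band-wise
#' condition contrasts (baseline vs favorite, favorite vs random non-favorite
#' control), and preference/behaviour statistics. When epoching yields no
#' epochs the downstream stages are skipped gracefully.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- if (!is.null(config$input_dir)) read_study(config$input_dir)
           else generate_study(config$generator)
  q <- study$questionnaire
  excluded <- screen_subjects(study$log)
  subjects <- setdiff(names(study$recordings), excluded$subject)

  report <- list(config = config, n_subjects = length(study$recordings),
                 excluded = excluded, skipped = character(0))
  class(report) <- "pipeline_report"

  sets <- list()
  artifact_fraction <- numeric(0)
  for (s in subjects) {
    rec <- study$recordings[[s]]
    filtered <- bandpass_filter(rec$eeg, rec$eeg_rate, config$low, config$high)
    mask <- detect_artifacts(rec, accel_thresh = config$accel_thresh,
                             amp_thresh = config$amp_thresh,
                             axis_rule = config$axis_rule,
                             dilate_s = config$dilate_s,
                             low = config$low, high = config$high,
                             filtered = filtered)
    artifact_fraction[s] <- mean(mask$mask)
    info <- q[q$subject == s, c("gender", "explained", "favorite_piece"), drop = FALSE]
    sets[[s]] <- extract_epochs(rec, mask, study$log, window = config$window,
                                overlap = config$overlap,
                                subject_info = info, data = filtered)
  }
  n_ep <- sum(vapply(sets, function(x) nrow(x$data), numeric(1)))
  report$artifact_fraction <- artifact_fraction
  if (n_ep == 0) {
    report$epoch_counts <- c(total = 0, BL = 0, FP = 0, NFP = 0)
    report$skipped <- c("spectra", "clustering", "bandstats")
    report$preference <- preference_report(study, config)
    write_report(report, config$out_dir)
    return(report)
  }
  epochs <- bind_epochs(sets)

  spec <- spectral_dataset(epochs, nw = config$nw, k = config$n_tapers,
                           baseline = config$baseline)
  lab <- spec$labels
  favorites <- setNames(PIECES[q$favorite_piece], q$subject)
  is_bl <- lab$condition == "BL"
  is_fp <- lab$condition == unname(favorites[lab$subject])
  nfp <- nfp_control(lab, as.list(favorites), seed = config$seed + 1L)
  nfp_rows <- attr(nfp, "epoch_rows")
  report$epoch_counts <- c(total = nrow(lab), BL = sum(is_bl), FP = sum(is_fp),
                           NFP = length(nfp_rows))
  report$epoch_duration_s <- epochs$duration_s
  report$nfp_selection <- nfp

  bl_spec <- subset_spectra(spec, which(is_bl))
  fp_spec <- subset_spectra(spec, which(is_fp))
  nfp_spec <- subset_spectra(spec, nfp_rows)

  cluster_one <- function(sp, include_explained, seed_off) {
    keep <- seeded_subsample(nrow(sp$values), config$max_cluster_epochs,
                             config$seed + seed_off)
    sp <- subset_spectra(sp, keep)
    vars <- epoch_variables(sp$labels, include_explained = include_explained)
    Kn2 <- select_k_variables(names(vars))
    X <- standardize_columns(sp$values, drop_constant = TRUE)
    chc <- select_k_ch(X, k_max = config$k_max)
    model <- ward_cluster(X, Kn2, linkage = chc$linkage)
    tab <- correspondence_table(model, vars)
    list(Kn1 = chc$k, Kn2 = Kn2, ch_curve = chc$curve, flatness = chc$flatness,
         model = model, table = tab, separability = separability_report(tab),
         n_used = length(keep))
  }
  if (sum(is_bl) >= 2) report$bl_cluster <- cluster_one(bl_spec, FALSE, 2L)
  if (sum(is_fp) >= 2) {
    both_expl <- length(unique(fp_spec$labels$explained)) == 2L
    report$fp_cluster <- cluster_one(fp_spec, both_expl, 3L)
  }

  report$contrasts <- list(
    BL_vs_FP = contrast_bands(bl_spec, fp_spec, var_equal = config$var_equal,
                              contrast = "BL_vs_FP"),
    FP_vs_NFP = if (length(nfp_rows) >= 8) {
      contrast_bands(fp_spec, nfp_spec, var_equal = config$var_equal,
                     contrast = "FP_vs_NFP")
    } else {
      NULL
    }
  )
  report$flags <- report_flags(report, config$alpha)
  report$preference <- preference_report(study, config)
  write_report(report, config$out_dir)
  report
}

# headline qualitative findings at level alpha
report_flags <- function(report, alpha) {
  flags <- list()
  ct <- report$contrasts$BL_vs_FP$tests
  frontal_beta <- ct[ct$band == "beta" & ct$sensor %in% FRONTAL, ]
  flags$frontal_beta_suppression <-
    all(frontal_beta$p < alpha) && all(frontal_beta$effect_db > 0) # BL minus FP > 0
  nf <- report$contrasts$FP_vs_NFP
  flags$fp_nfp_beta_difference <- if (is.null(nf)) NA else {
    mean(nf$tests$p[nf$tests$band == "beta" & nf$tests$sensor %in% FRONTAL]) < alpha
  }
  if (!is.null(report$fp_cluster)) {
    sep <- report$fp_cluster$separability
    pick <- function(a, b) sep[(sep$var_a == a & sep$var_b == b) |
                                 (sep$var_a == b & sep$var_b == a), ]
    expl <- pick("explained", "not_explained")
    flags$explained_non_separable <- if (nrow(expl)) !expl$separable else NA
    above <- report$fp_cluster$table$above_average
    noise <- report$fp_cluster$table$noise_cluster
    if (!is.na(noise)) above <- above[, -noise, drop = FALSE]
    fr <- above["AF7", ] | above["AF8", ]
    po <- above["TP9", ] | above["TP10", ]
    flags$frontal_posterior_distinct <- !any(fr & po, na.rm = TRUE)
  }
  flags
}

preference_report <- function(study, config) {
  q <- study$questionnaire
  if (nrow(q) == 0) return(NULL)
  out <- list(appreciation = appreciation_summary(study$log))
  for (g in c("male", "female")) {
    rows <- q$gender == g
    if (!any(rows)) next
    qq <- q[rows, , drop = FALSE]
    cohort <- qq$age >= 18 & qq$age <= 30
    out[[g]] <- list()
    if (any(cohort)) {
      out[[g]]$cohort <- preference_distribution(qq, cohort, label = paste(g, "cohort"))
    }
    if (any(cohort) && any(!cohort)) {
      split <- cohort_split(qq, cohort)
      out[[g]]$population <- split$reference
      out[[g]]$shift <- distribution_shift_test(split$cohort, split$reference,
                                                seed = config$seed + 5L)
    }
  }
  out
}

write_report <- function(report, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  cfg$generator <- unclass(cfg$generator)
  yaml::write_yaml(lapply(unclass(cfg), function(x) if (is.null(x)) NA else x),
                   file.path(out_dir, "config_resolved.yaml"))
  write.csv(data.frame(measure = names(report$epoch_counts),
                       count = as.integer(report$epoch_counts)),
            file.path(out_dir, "epoch_counts.csv"), row.names = FALSE)
  for (nm in c("bl_cluster", "fp_cluster")) {
    cl <- report[[nm]]
    if (is.null(cl)) next
    write.csv(cl$ch_curve, file.path(out_dir, paste0(nm, "_ch_curve.csv")),
              row.names = FALSE)
    write.csv(data.frame(variable = rownames(cl$table$percent),
                         round(cl$table$percent, 6)),
              file.path(out_dir, paste0(nm, "_correspondence.csv")), row.names = FALSE)
    write.csv(cl$separability, file.path(out_dir, paste0(nm, "_separability.csv")),
              row.names = FALSE)
  }
  for (nm in names(report$contrasts)) {
    if (!is.null(report$contrasts[[nm]])) {
      write.csv(report$contrasts[[nm]]$tests,
                file.path(out_dir, paste0("contrast_", nm, ".csv")), row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  subjects: %d (%d excluded by log flags)\n",
              x$n_subjects, nrow(x$excluded)))
  if (!is.null(x$epoch_counts)) {
    cat(sprintf("  epochs: total %d | BL %d | FP %d | NFP %d (%.2f s each)\n",
                x$epoch_counts["total"], x$epoch_counts["BL"], x$epoch_counts["FP"],
                x$epoch_counts["NFP"], x$epoch_duration_s %||% NA))
  }
  if (length(x$skipped)) {
    cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
    return(invisible(x))
  }
  if (!is.null(x$bl_cluster)) {
    cat(sprintf("  BL clustering: Kn1(CH) = %d, Kn2(vars+1) = %d\n",
                x$bl_cluster$Kn1, x$bl_cluster$Kn2))
  }
  if (!is.null(x$fp_cluster)) {
    cat(sprintf("  FP clustering: Kn1(CH) = %d, Kn2(vars+1) = %d\n",
                x$fp_cluster$Kn1, x$fp_cluster$Kn2))
  }
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    if (is.null(ct)) next
    s <- ct$summary
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s avg p=%.4g", s$band, s$avg_p), collapse = ", ")))
  }
  if (!is.null(x$flags)) {
    for (nm in names(x$flags)) {
      cat(sprintf("  %-28s %s\n", nm, format(x$flags[[nm]])))
    }
  }
  invisible(x)
}
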