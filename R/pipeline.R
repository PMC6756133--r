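# Study orchestration: per-subject preprocessing + decoding, and the
# study-level statistical battery.

#' Analysis configuration
#'
#' Bundles every tunable of the study pipeline. Serialises losslessly to
#' JSON ([write_config()] / [read_config()]).
#'
#' @param band `"delta"` (0.5-4 Hz), `"theta"` (4-8 Hz) or a numeric pair.
#' @param lags decoder lag window in ms (preset `c(0, 75)` or `c(0, 500)`).
#' @param trf_lags forward-TRF lag window in ms (default `c(0, 500)`).
#' @param fs_analysis final analysis rate in Hz (default 128).
#' @param blank_uv amplitude blanking threshold (default 500).
#' @param mwf apply the multichannel Wiener filter (default TRUE).
#' @param mwf_delay MWF delay span in samples (default 3).
#' @param n_boot bootstrap replicates per trial (default 200).
#' @param block_s bootstrap block length in seconds (default 5).
#' @param k_bins number of SNR bins for the statistics (default 7).
#' @param n_perm permutations for the paired and cluster tests (default 1000).
#' @param cluster_alpha cluster-forming alpha (default 0.05).
#' @param training_condition metadata condition tag of the decoder-training
#'   trial (default `"story"`).
#' @param seed integer seed for all stochastic steps.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(band = "delta", lags = c(0, 75),
                            trf_lags = c(0, 500), fs_analysis = 128,
                            blank_uv = 500, mwf = TRUE, mwf_delay = 3L,
                            n_boot = 200L, block_s = 5, k_bins = 7L,
                            n_perm = 1000L, cluster_alpha = 0.05,
                            training_condition = "story", seed = 1L) {
  structure(list(band = band, lags = lags, trf_lags = trf_lags,
                 fs_analysis = fs_analysis, blank_uv = blank_uv,
                 mwf = mwf, mwf_delay = as.integer(mwf_delay),
                 n_boot = as.integer(n_boot), block_s = block_s,
                 k_bins = as.integer(k_bins), n_perm = as.integer(n_perm),
                 cluster_alpha = cluster_alpha,
                 training_condition = training_condition,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, obj)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

# Shared cleaning chain for one trial: blank, MWF, re-reference, band-pass,
# resample; the identical band-pass/resample path is applied to the
# envelope.
preprocess_trial <- function(trial, config) {
  eeg <- blank_and_interpolate(trial$eeg, config$blank_uv)
  if (isTRUE(config$mwf)) {
    eeg <- suppressWarnings(
      mwf_denoise(eeg, delay_span = config$mwf_delay))$eeg
  }
  eeg <- rereference_average(eeg)
  eeg <- bandpass(eeg, config$band)
  eeg <- resample_to(eeg, config$fs_analysis)
  env <- bandpass(trial$envelope, config$band)
  env <- resample_to(env, config$fs_analysis)
  n <- min(ncol(eeg$data), length(env$samples))
  eeg$data <- eeg$data[, seq_len(n), drop = FALSE]
  env$samples <- env$samples[seq_len(n)]
  list(eeg = eeg, envelope = env, meta = trial$meta)
}

#' Analyse one subject
#'
#' Preprocesses the training trial, trains the backward decoder on it,
#' then reconstructs and scores every test trial; repeated presentations at
#' the same condition and SNR are averaged into one row. A forward TRF per
#' condition is estimated from the highest-SNR trial of that condition.
#'
#' @param subject_data list with `training` and `trials` (as produced by
#'   [gen_subject()] or [read_study()]), or a subject directory path.
#' @param config an [analysis_config()].
#' @return list with `tracking` (data.frame: subject, condition, snr,
#'   rho, ci_low, ci_high, n_boot, band, lags) and `trfs` (named list of
#'   per-condition [train_forward()] TRFs).
#' @export
run_subject <- function(subject_data, config = analysis_config()) {
  if (is.character(subject_data)) {
    root <- dirname(subject_data)
    tmp <- read_study(root)
    keep <- basename(subject_data) == basename(sort(list.dirs(root,
                                                              recursive = FALSE)))
    subject_data <- tmp$subjects[[which(keep)]]
  }
  if (is.null(subject_data$training))
    stop_invalid("subject has no training trial")
  sid <- if (!is.null(subject_data$subject)) subject_data$subject else NA
  train <- preprocess_trial(subject_data$training, config)
  ls_dec <- lag_spec(config$lags[1], config$lags[2], config$fs_analysis)
  decoder <- train_backward(train$eeg, train$envelope, ls_dec)
  rows <- list()
  failures <- 0L
  per_cond_best <- list()
  for (i in seq_along(subject_data$trials)) {
    res <- tryCatch({
      tr <- preprocess_trial(subject_data$trials[[i]], config)
      shat <- reconstruct(decoder, tr$eeg)
      sc <- bootstrap_spearman(tr$envelope, shat, n_boot = config$n_boot,
                               seed = derive_seed(config$seed, sid, i),
                               block_len = as.integer(config$block_s *
                                                        config$fs_analysis))
      list(tr = tr, sc = sc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("trial %d skipped: %s", i, conditionMessage(res)))
      failures <- failures + 1L
      next
    }
    meta <- res$tr$meta
    rows[[length(rows) + 1L]] <- data.frame(
      subject = sid, condition = meta$condition, snr = meta$snr,
      rho = res$sc$rho_median, ci_low = res$sc$ci_low,
      ci_high = res$sc$ci_high, n_boot = res$sc$n_boot)
    key <- meta$condition
    if (is.null(per_cond_best[[key]]) ||
        isTRUE(meta$snr >= per_cond_best[[key]]$snr)) {
      per_cond_best[[key]] <- list(snr = meta$snr, tr = res$tr)
    }
  }
  tab <- do.call(rbind, rows)
  # average repeated presentations of the same condition x SNR
  agg <- stats::aggregate(cbind(rho, ci_low, ci_high) ~ subject + condition +
                            snr, data = tab, FUN = mean)
  agg$n_boot <- config$n_boot
  agg$band <- paste(band_preset(config$band), collapse = "-")
  agg$lags <- paste(config$lags, collapse = "-")
  ls_trf <- lag_spec(config$trf_lags[1], config$trf_lags[2],
                     config$fs_analysis)
  trfs <- lapply(per_cond_best, function(b)
    train_forward(b$tr$envelope, b$tr$eeg, ls_trf))
  list(tracking = agg, trfs = trfs, n_failed = failures)
}

#' Analyse a full study
#'
#' Runs [run_subject()] for every subject (generating subjects lazily when
#' a [study_config()] is supplied), then assembles the study-level
#' statistics: SNR binning, pooled SNR-tracking Spearman correlations per
#' condition with a dependent-correlation comparison, per-bin paired
#' sign-flip permutation tests (Holm adjusted), per-bin Brown-Forsythe
#' spread tests, neural psychometric fits per condition, and the
#' channel x lag cluster permutation test between the first two conditions'
#' TRFs.
#'
#' @param study a `synthetic_study`, a [study_config()] (lazy generation),
#'   or a directory path from [write_study()].
#' @param config an [analysis_config()].
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return object of class `study_report`.
#' @export
run_study <- function(study, config = analysis_config(), out_dir = NULL) {
  lazy_cfg <- NULL
  if (is.character(study)) study <- read_study(study)
  if (inherits(study, "study_config")) {
    lazy_cfg <- study
    n_sub <- lazy_cfg$n_subjects
  } else {
    n_sub <- length(study$subjects)
  }
  if (n_sub < 2L) stop_invalid("a study needs at least 2 subjects")
  tracking <- list()
  trf_sets <- list()
  for (i in seq_len(n_sub)) {
    sub <- if (is.null(lazy_cfg)) study$subjects[[i]] else
      gen_subject(lazy_cfg, i)
    res <- run_subject(sub, config)
    tracking[[i]] <- res$tracking
    for (cond in names(res$trfs))
      trf_sets[[cond]][[length(trf_sets[[cond]]) + 1L]] <- res$trfs[[cond]]
    rm(sub)
  }
  tracking <- do.call(rbind, tracking)
  conditions <- unique(tracking$condition)
  # SNR bins over all finite SNRs
  finite_snr <- tracking$snr[is.finite(tracking$snr)]
  k <- min(config$k_bins, length(unique(finite_snr)))
  bins <- bin_snrs(sort(unique(finite_snr)), k = k,
                   seed = derive_seed(config$seed, 7))
  snr_bin_of <- function(snr) bins$labels[match(snr, sort(unique(finite_snr)))]
  tracking$snr_bin <- snr_bin_of(tracking$snr)
  tracking$snr_bin_center <- bins$centers[tracking$snr_bin]
  report <- list(tracking = tracking, bins = bins,
                 config = config, config_hash = config_hash(config),
                 n_subjects = n_sub)
  # pooled SNR-tracking correlations per condition
  pooled <- lapply(conditions, function(cond) {
    d <- tracking[tracking$condition == cond & is.finite(tracking$snr), ]
    suppressWarnings(cor(d$snr, d$rho, method = "spearman"))
  })
  names(pooled) <- conditions
  report$snr_correlations <- unlist(pooled)
  if (length(conditions) >= 2L) {
    c1 <- conditions[1]; c2 <- conditions[2]
    wide_rho <- merge(
      tracking[tracking$condition == c1,
               c("subject", "snr_bin", "snr_bin_center", "rho")],
      tracking[tracking$condition == c2, c("subject", "snr_bin", "rho")],
      by = c("subject", "snr_bin"), suffixes = c("_a", "_b"))
    # dependent-correlation comparison on matched observations
    ok <- is.finite(wide_rho$snr_bin_center)
    n_obs <- sum(ok)
    r_a <- cor(wide_rho$snr_bin_center[ok], wide_rho$rho_a[ok],
               method = "spearman")
    r_b <- cor(wide_rho$snr_bin_center[ok], wide_rho$rho_b[ok],
               method = "spearman")
    r_ab <- cor(wide_rho$rho_a[ok], wide_rho$rho_b[ok], method = "spearman")
    report$correlation_comparison <- c(
      list(r_attention = r_a, r_other = r_b, r_between = r_ab, n = n_obs),
      compare_dependent_correlations(r_a, r_b, r_ab, n_obs))
    # per-bin paired permutation tests
    xa <- stats::reshape(wide_rho[, c("subject", "snr_bin", "rho_a")],
                         idvar = "subject", timevar = "snr_bin",
                         direction = "wide")
    xb <- stats::reshape(wide_rho[, c("subject", "snr_bin", "rho_b")],
                         idvar = "subject", timevar = "snr_bin",
                         direction = "wide")
    xa <- as.matrix(xa[order(xa$subject), -1, drop = FALSE])
    xb <- as.matrix(xb[order(xb$subject), -1, drop = FALSE])
    bin_ids <- as.integer(sub(".*\\.", "", colnames(xa)))
    ord <- order(bin_ids)
    xa <- xa[, ord, drop = FALSE]; xb <- xb[, ord, drop = FALSE]
    if (!anyNA(xa) && !anyNA(xb) && nrow(xa) >= 2L) {
      pt <- paired_permutation_by_snr(xa, xb,
                                      n_perm = max(1000L, config$n_perm),
                                      seed = derive_seed(config$seed, 11))
      report$per_bin_tests <- data.frame(
        snr_bin = sort(bin_ids), center = bins$centers[sort(bin_ids)],
        mean_diff = pt$observed, p_raw = pt$p_raw,
        p_adjusted = pt$p_adjusted)
    }
    # spread comparison per bin
    report$spread_tests <- do.call(rbind, lapply(sort(unique(bin_ids)),
      function(b) {
        g1 <- wide_rho$rho_a[wide_rho$snr_bin == b]
        g2 <- wide_rho$rho_b[wide_rho$snr_bin == b]
        bf <- brown_forsythe(list(g1, g2))
        data.frame(snr_bin = b, statistic = bf$statistic, p = bf$p.value)
      }))
    # cluster permutation on the two conditions' TRFs
    if (length(trf_sets[[c1]]) == length(trf_sets[[c2]]) &&
        length(trf_sets[[c1]]) >= 5L) {
      report$cluster <- cluster_permutation(
        trf_sets[[c1]], trf_sets[[c2]], adjacency = channel_adjacency(),
        cluster_alpha = config$cluster_alpha, n_perm = config$n_perm,
        seed = derive_seed(config$seed, 13))
    }
  } else {
    report$notice <- "single condition: comparison analyses skipped"
  }
  # neural psychometric fit per condition (pooled subject x SNR points)
  report$neural_srt <- lapply(setNames(conditions, conditions),
    function(cond) {
      d <- tracking[tracking$condition == cond & is.finite(tracking$snr), ]
      if (length(unique(d$snr)) < 4L) return(NULL)
      fit_psychometric(d$snr, d$rho, fix_rates = FALSE)
    })
  report$trf_sets <- trf_sets
  class(report) <- "study_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study report: %d subjects, config %s\n", x$n_subjects,
              substr(x$config_hash, 1, 8)))
  cat("SNR-tracking Spearman correlations:\n")
  print(round(x$snr_correlations, 3))
  if (!is.null(x$per_bin_tests)) {
    cat("per-bin paired permutation tests (Holm adjusted):\n")
    print(x$per_bin_tests, row.names = FALSE)
  }
  if (!is.null(x$neural_srt)) {
    for (cond in names(x$neural_srt)) {
      f <- x$neural_srt[[cond]]
      if (!is.null(f))
        cat(sprintf("neural SRT [%s]: %.2f dB SNR\n", cond, f$alpha))
    }
  }
  if (!is.null(x$cluster)) print(x$cluster)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$tracking, file.path(out_dir, "tracking.csv"))
  if (!is.null(report$per_bin_tests))
    data.table::fwrite(report$per_bin_tests,
                       file.path(out_dir, "per_bin_tests.csv"))
  if (!is.null(report$spread_tests))
    data.table::fwrite(report$spread_tests,
                       file.path(out_dir, "spread_tests.csv"))
  if (!is.null(report$cluster)) {
    cl <- report$cluster$clusters
    cl$channels <- vapply(cl$channels, paste, "", collapse = ";")
    data.table::fwrite(cl, file.path(out_dir, "clusters.csv"))
  }
  summary_obj <- list(
    config_hash = report$config_hash,
    n_subjects = report$n_subjects,
    snr_correlations = as.list(report$snr_correlations),
    correlation_comparison = report$correlation_comparison,
    neural_srt = lapply(report$neural_srt, function(f)
      if (is.null(f)) NULL else list(alpha = f$alpha, beta = f$beta,
                                     guess = f$guess, lapse = f$lapse)))
  jsonlite::write_json(summary_obj, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(report$config, file.path(out_dir, "config.json"))
  invisible(out_dir)
}
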