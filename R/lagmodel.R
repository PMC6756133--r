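# Backward (stimulus-reconstruction) and forward (TRF) linear models with
# ridge regression, bootstrapped Spearman tracking scores and TRF peaks.

#' Post-stimulus lag window specification
#'
#' @param start_ms,end_ms lag window in milliseconds (post-stimulus).
#' @param fs sampling rate in Hz at which the lags are realized.
#' @return object of class `lag_spec` with the integer sample lags.
#' @export
lag_spec <- function(start_ms, end_ms, fs) {
  check_scalar_number(fs, "fs", positive = TRUE)
  if (!(start_ms >= 0 && start_ms < end_ms))
    stop_invalid("need 0 <= start_ms < end_ms")
  lags <- seq(floor(start_ms / 1000 * fs), floor(end_ms / 1000 * fs))
  structure(list(start_ms = start_ms, end_ms = end_ms, fs = fs,
                 lags = as.integer(lags), n_lags = length(lags),
                 lag_ms = lags / fs * 1000),
            class = "lag_spec")
}

#' @export
print.lag_spec <- function(x, ...) {
  cat(sprintf("lags %g-%g ms @ %g Hz: %d samples\n",
              x$start_ms, x$end_ms, x$fs, x$n_lags))
  invisible(x)
}

#' Build the lagged design matrix of neural responses
#'
#' Column `(n, tau)` holds channel `n` advanced by `tau` samples, so row `t`
#' contains the post-stimulus EEG context used to reconstruct the envelope
#' at `t`. Entries beyond the recording are zero-padded, keeping the number
#' of rows equal to the number of samples.
#'
#' @param eeg an [eeg_recording()] (or channels x samples matrix).
#' @param lagspec a [lag_spec()]; its rate must match the recording.
#' @return time x (channels * lags) matrix; lags vary fastest within a
#'   channel block.
#' @export
lag_matrix <- function(eeg, lagspec) {
  x <- if (inherits(eeg, "eeg_recording")) eeg$data else eeg
  if (inherits(eeg, "eeg_recording") && abs(eeg$fs - lagspec$fs) > 1e-9)
    stop_invalid("lag specification rate does not match the recording")
  n <- ncol(x); C <- nrow(x)
  if (max(lagspec$lags) >= n)
    stop_invalid("lag window longer than the recording")
  out <- matrix(0, n, C * lagspec$n_lags)
  for (ci in seq_len(C)) {
    for (k in seq_len(lagspec$n_lags)) {
      tau <- lagspec$lags[k]
      col <- (ci - 1L) * lagspec$n_lags + k
      out[1:(n - tau), col] <- x[ci, (1 + tau):n]
    }
  }
  out
}

# Lagged design for the forward model: column tau holds the envelope
# *delayed* by tau samples (the response at t depends on the stimulus at
# t - tau). Zero-padded at the start.
lag_matrix_forward <- function(env, lagspec) {
  s <- if (inherits(env, "envelope_signal")) env$samples else env
  n <- length(s)
  out <- matrix(0, n, lagspec$n_lags)
  for (k in seq_len(lagspec$n_lags)) {
    tau <- lagspec$lags[k]
    out[(1 + tau):n, k] <- s[1:(n - tau)]
  }
  out
}

ridge_solve <- function(X, Y, lambda = NULL) {
  XtX <- crossprod(X)
  if (is.null(lambda)) lambda <- max(abs(XtX))
  XtY <- crossprod(X, Y)
  A <- XtX
  diag(A) <- diag(A) + lambda
  list(w = solve(A, XtY), lambda = lambda)
}

#' Train a backward decoder (envelope reconstruction)
#'
#' Solves the ridge normal equations for the linear map from lagged,
#' z-scored EEG to the z-scored stimulus envelope. By default the ridge
#' parameter is the maximal absolute entry of the autocorrelation matrix of
#' the lagged design.
#'
#' @param eeg an [eeg_recording()].
#' @param env an [envelope_signal()] of the same duration and rate.
#' @param lagspec a [lag_spec()].
#' @param lambda optional ridge parameter override; `lambda = 0` requires a
#'   full-rank design.
#' @return object of class `backward_decoder` with `weights`
#'   (channels x lags), `lambda`, `lagspec` and `band`.
#' @export
train_backward <- function(eeg, env, lagspec, lambda = NULL) {
  if (abs(eeg$fs - env$fs) > 1e-9)
    stop_invalid("EEG and envelope rates differ")
  if (ncol(eeg$data) != length(env$samples))
    stop_invalid("EEG and envelope durations differ")
  zd <- t(zscore(t(eeg$data))) # z-score each channel, then lag
  X <- lag_matrix(zd, lagspec)
  s <- zscore(env$samples)
  if (!is.null(lambda) && lambda == 0) {
    XtX <- crossprod(X)
    if (rcond_est(XtX) < 1e-12)
      stop_invalid("design is rank deficient; a zero ridge cannot be solved")
  }
  fit <- ridge_solve(X, s, lambda)
  w <- matrix(fit$w, nrow = nrow(eeg$data), ncol = lagspec$n_lags,
              byrow = TRUE)
  rownames(w) <- eeg$labels
  structure(list(weights = w, lambda = fit$lambda, lagspec = lagspec,
                 band = eeg$band, labels = eeg$labels),
            class = "backward_decoder")
}

rcond_est <- function(A) {
  e <- tryCatch(range(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values)),
                error = function(e) c(0, 1))
  if (e[2] == 0) 0 else e[1] / e[2]
}

#' @export
print.backward_decoder <- function(x, ...) {
  cat(sprintf("backward decoder: %d channels x %d lags (%g-%g ms), lambda=%.3g\n",
              nrow(x$weights), ncol(x$weights), x$lagspec$start_ms,
              x$lagspec$end_ms, x$lambda))
  invisible(x)
}

#' Reconstruct the stimulus envelope from EEG
#'
#' Computes \eqn{\hat s(t) = \sum_n \sum_\tau g(n,\tau)\, R(t+\tau, n)} by
#' per-channel correlation with the decoder weights. EEG channels are
#' z-scored with the recording's own statistics, matching training.
#'
#' @param decoder a [train_backward()] decoder.
#' @param eeg an [eeg_recording()] at the decoder's rate.
#' @return an [envelope_signal()] with the reconstruction (z-units).
#' @export
reconstruct <- function(decoder, eeg) {
  if (nrow(eeg$data) != nrow(decoder$weights))
    stop_invalid("channel count does not match the decoder")
  if (abs(eeg$fs - decoder$lagspec$fs) > 1e-9)
    stop_invalid("EEG rate does not match the decoder's lag specification")
  n <- ncol(eeg$data)
  L <- decoder$lagspec$n_lags
  s0 <- decoder$lagspec$lags[1]
  shat <- numeric(n)
  for (ci in seq_len(nrow(eeg$data))) {
    g <- decoder$weights[ci, ]
    if (all(g == 0)) next
    x <- zscore(eeg$data[ci, ])
    # channel advanced by the first lag, zero-padded beyond the recording
    xp <- c(if (s0 < n) x[(1 + s0):n] else numeric(0), numeric(min(s0, n)))
    # u[t] = sum_j g[j] xp[t + j - 1] via a reversed one-sided convolution
    z <- rev(c(xp, numeric(L - 1L)))
    v <- as.numeric(stats::filter(z, g, method = "convolution", sides = 1))
    shat <- shat + v[n + L - seq_len(n)]
  }
  envelope_signal(shat, eeg$fs)
}

#' Train a forward temporal response function
#'
#' Per-channel ridge regression of the (z-scored) EEG on the lagged,
#' z-scored stimulus envelope; the same ridge rule is applied to the
#' envelope autocorrelation matrix.
#'
#' @param env an [envelope_signal()].
#' @param eeg an [eeg_recording()] of the same duration and rate.
#' @param lagspec a [lag_spec()].
#' @param lambda optional ridge override.
#' @param lambda_scale when `lambda` is `NULL`, the ridge parameter is
#'   `lambda_scale` times the maximal absolute entry of the envelope
#'   autocorrelation matrix (default 0.01). The forward model has only one
#'   regressor per lag, so the full decoder-style ridge badly over-smooths
#'   the kernel; a light ridge preserves peak morphology while keeping the
#'   solve well conditioned.
#' @return object of class `forward_trf` with `kernel`
#'   (channels x lags, z-units per envelope z-unit) and `lag_ms`.
#' @export
train_forward <- function(env, eeg, lagspec, lambda = NULL,
                          lambda_scale = 0.01) {
  if (abs(eeg$fs - env$fs) > 1e-9)
    stop_invalid("EEG and envelope rates differ")
  if (ncol(eeg$data) != length(env$samples))
    stop_invalid("EEG and envelope durations differ")
  X <- lag_matrix_forward(zscore(env$samples), lagspec)
  if (is.null(lambda)) lambda <- lambda_scale * max(abs(crossprod(X)))
  if (all(abs(eeg$data) < .Machine$double.eps)) {
    k <- matrix(0, nrow(eeg$data), lagspec$n_lags)
  } else {
    Y <- zscore(t(eeg$data))
    fit <- ridge_solve(X, Y, lambda)
    k <- t(fit$w)
  }
  rownames(k) <- eeg$labels
  structure(list(kernel = k, lag_ms = lagspec$lag_ms, lagspec = lagspec,
                 labels = eeg$labels),
            class = "forward_trf")
}

#' @export
print.forward_trf <- function(x, ...) {
  cat(sprintf("forward TRF: %d channels x %d lags (%g-%g ms)\n",
              nrow(x$kernel), ncol(x$kernel), min(x$lag_ms), max(x$lag_ms)))
  invisible(x)
}

#' Locate P1/N1/P2 peaks in a TRF
#'
#' Searches the channel-averaged kernel (or a channel subset) for the
#' maximum (P1, P2) or minimum (N1) within per-peak latency windows.
#'
#' @param trf a [train_forward()] TRF, or a `reference_kernel`.
#' @param windows named list of `(low, high)` ms windows; defaults to
#'   P1 (20, 70), N1 (60, 120), P2 (120, 250).
#' @param channels optional channel labels to average over.
#' @param interpolate refine the peak latency by quadratic interpolation
#'   through the three samples around the extremum (default TRUE); with
#'   `FALSE` the latency is the raw lag-grid sample.
#' @return data.frame with `label`, `latency_ms`, `amplitude`.
#' @export
trf_peaks <- function(trf,
                      windows = list(P1 = c(20, 70), N1 = c(60, 120),
                                     P2 = c(120, 250)),
                      channels = NULL, interpolate = TRUE) {
  k <- trf$kernel
  lag_ms <- trf$lag_ms
  if (!is.null(channels)) {
    if (!all(channels %in% rownames(k)))
      stop_invalid("unknown channel labels")
    k <- k[channels, , drop = FALSE]
  }
  avg <- colMeans(k)
  out <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    sel <- which(lag_ms >= w[1] & lag_ms <= w[2])
    if (length(sel) == 0L)
      stop_invalid(sprintf("window %s contains no lags", nm))
    i <- if (nm == "N1") sel[which.min(avg[sel])] else sel[which.max(avg[sel])]
    lat <- lag_ms[i]
    if (interpolate && i > 1L && i < length(avg)) {
      y0 <- avg[i - 1L]; y1 <- avg[i]; y2 <- avg[i + 1L]
      den <- y0 - 2 * y1 + y2
      if (abs(den) > .Machine$double.eps) {
        delta <- 0.5 * (y0 - y2) / den
        if (abs(delta) <= 1) lat <- lat + delta * (lag_ms[2] - lag_ms[1])
      }
    }
    data.frame(label = nm, latency_ms = lat, amplitude = avg[i])
  })
  do.call(rbind, out)
}

#' Bootstrapped Spearman tracking score
#'
#' Moving-block bootstrap of the paired samples of two equal-length signals:
#' blocks of `block_len` samples are resampled with replacement (the same
#' blocks from both signals), the Spearman correlation is computed per
#' replicate, and the median with the 2.5-97.5 percentile interval is
#' reported.
#'
#' @param a,b numeric vectors or [envelope_signal()]s of equal length.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param block_len block length in samples; defaults to 5 s when a rate is
#'   available, else 1/20 of the signal.
#' @return object of class `tracking_score` with `rho_median`, `ci_low`,
#'   `ci_high`, `n_boot`.
#' @export
bootstrap_spearman <- function(a, b, n_boot = 1000L, seed = 1L,
                               block_len = NULL) {
  fs <- NULL
  if (inherits(a, "envelope_signal")) { fs <- a$fs; a <- a$samples }
  if (inherits(b, "envelope_signal")) { fs <- if (is.null(fs)) b$fs else fs; b <- b$samples }
  if (length(a) != length(b)) stop_invalid("signals must have equal length")
  if (sd(a) == 0 || sd(b) == 0)
    stop_invalid("correlation undefined for a constant signal")
  n <- length(a)
  if (is.null(block_len))
    block_len <- if (!is.null(fs)) max(2L, as.integer(5 * fs)) else
      max(2L, n %/% 20L)
  block_len <- min(block_len, n)
  n_blocks <- max(1L, as.integer(ceiling(n / block_len)))
  if (n < 2L * block_len && n > 4L) {
    block_len <- n %/% 2L
    n_blocks <- 2L
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  starts_max <- n - block_len + 1L
  rho <- vapply(seq_len(n_boot), function(i) {
    st <- sample.int(starts_max, n_blocks, replace = TRUE)
    idx <- as.vector(outer(0:(block_len - 1L), st, `+`))
    suppressWarnings(cor(a[idx], b[idx], method = "spearman"))
  }, 0)
  rho <- rho[is.finite(rho)]
  qs <- quantile(rho, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(rho_median = median(rho), ci_low = qs[1], ci_high = qs[2],
                 n_boot = n_boot, block_len = block_len),
            class = "tracking_score")
}

#' @export
print.tracking_score <- function(x, ...) {
  cat(sprintf("tracking rho = %.3f [%.3f, %.3f] (%d bootstraps)\n",
              x$rho_median, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
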