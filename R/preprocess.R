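# EEG cleaning: amplitude blanking with linear interpolation, multichannel
# Wiener filtering of ocular artifacts, and average re-referencing.

#' Blank supra-threshold samples and interpolate linearly
#'
#' Every sample whose absolute amplitude exceeds `threshold` is replaced,
#' per channel, by linear interpolation between the nearest surviving
#' neighbours; runs touching a recording edge are held at the nearest
#' surviving value. All sub-threshold samples are returned bit-identical.
#'
#' @param eeg an [eeg_recording()].
#' @param threshold blanking threshold in microvolts (default 500).
#' @return the blanked recording.
#' @export
blank_and_interpolate <- function(eeg, threshold = 500) {
  check_scalar_number(threshold, "threshold", positive = TRUE)
  x <- eeg$data
  n <- ncol(x)
  for (ch in seq_len(nrow(x))) {
    bad <- abs(x[ch, ]) > threshold
    if (!any(bad)) next
    if (all(bad))
      stop_invalid(sprintf(
        "channel %s exceeds the threshold everywhere; nothing to interpolate from",
        eeg$labels[ch]))
    good <- which(!bad)
    x[ch, bad] <- approx(good, x[ch, good], xout = which(bad),
                         rule = 2)$y
  }
  eeg$data <- x
  eeg
}

#' Multichannel Wiener filter for ocular artifacts
#'
#' Marks artifact samples where the instantaneous power of any listed
#' frontal channel exceeds `power_factor` times that channel's time-averaged
#' power, then estimates a spatio-temporal Wiener filter from the artifact
#' and clean covariance matrices (generalized eigenvalue decomposition,
#' keeping components whose artifact-to-clean power ratio exceeds 1) and
#' subtracts the estimated artifact from every channel.
#'
#' @param eeg an [eeg_recording()].
#' @param frontal frontal channel labels used for detection; defaults to
#'   [frontal_labels()] intersected with the recording's channels.
#' @param power_factor detection threshold as a multiple of the per-channel
#'   mean power (default 5).
#' @param delay_span number of delayed copies on each side used in the
#'   spatio-temporal extension (default 3 samples).
#' @return list with the cleaned `eeg` and the logical artifact `mask`.
#' @export
mwf_denoise <- function(eeg, frontal = NULL, power_factor = 5,
                        delay_span = 3L) {
  if (is.null(frontal)) frontal <- intersect(frontal_labels(), eeg$labels)
  if (!all(frontal %in% eeg$labels))
    stop_invalid("`frontal` must be a subset of the recording's labels")
  if (length(frontal) == 0L) stop_invalid("no frontal channels available")
  x <- eeg$data
  fr <- x[frontal, , drop = FALSE]
  pw <- fr^2
  mask <- colSums(pw > power_factor * rowMeans(pw)) > 0L
  if (!any(mask)) {
    warning("no artifact samples detected; returning input unchanged")
    return(list(eeg = eeg, mask = mask))
  }
  if (all(mask))
    stop_invalid("every sample flagged as artifact; cannot estimate clean covariance")
  C <- nrow(x); n <- ncol(x); L <- as.integer(delay_span)
  # spatio-temporal extension: stack delayed copies (-L..L)
  shifts <- (-L):L
  ext <- matrix(0, n, C * length(shifts))
  for (k in seq_along(shifts)) {
    s <- shifts[k]
    cols <- (k - 1L) * C + seq_len(C)
    if (s >= 0) {
      ext[(1 + s):n, cols] <- t(x)[1:(n - s), , drop = FALSE]
    } else {
      ext[1:(n + s), cols] <- t(x)[(1 - s):n, , drop = FALSE]
    }
  }
  S_all <- crossprod(ext)
  S_art <- crossprod(ext[mask, , drop = FALSE])
  Ryy <- S_art / sum(mask)
  Rvv <- (S_all - S_art) / sum(!mask)
  # joint diagonalisation via Cholesky whitening of the clean covariance
  Rvv <- Rvv + diag(1e-10 * mean(diag(Rvv)), ncol(Rvv))
  Lc <- chol(Rvv) # upper triangular: Rvv = t(Lc) %*% Lc
  # whitened symmetric form of the generalized eigenvalue problem
  M <- forwardsolve(t(Lc), t(forwardsolve(t(Lc), Ryy)))
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- eg$values
  U <- eg$vectors
  X <- backsolve(Lc, U) # columns: generalized eigenvectors
  d <- pmax(lam - 1, 0) / lam
  d[lam <= 1] <- 0
  # artifact estimate for the lag-0 channel block only
  lag0 <- L * C + seq_len(C)
  Xinv_t <- t(solve(X)) # = X^-T, rows of interest only after transpose
  Fr <- (Xinv_t[lag0, , drop = FALSE] * rep(d, each = C)) %*% t(X)
  art <- Fr %*% t(ext)
  eeg$data <- x - art
  list(eeg = eeg, mask = mask)
}

#' Re-reference to the common average
#'
#' Subtracts the per-sample mean across channels; an idempotent linear
#' projection (applying it twice equals applying it once).
#'
#' @param eeg an [eeg_recording()].
#' @return the re-referenced recording with `reference = "average"`.
#' @export
rereference_average <- function(eeg) {
  eeg$data <- sweep(eeg$data, 2L, colMeans(eeg$data))
  eeg$reference <- "average"
  eeg
}
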