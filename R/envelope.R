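# Speech envelope extraction: ERB-spaced gammatone filterbank followed by
# sample-wise power-law compression and averaging across subbands.

#' ERB-rate of a frequency (Glasberg & Moore)
#'
#' `erb_rate()` maps frequency in Hz to the ERB-number scale
#' \eqn{E(f) = 21.4 \log_{10}(0.00437 f + 1)}; `erb_rate_inv()` is its
#' inverse and `erb_bandwidth()` the equivalent rectangular bandwidth at
#' `f`, \eqn{24.7 (0.00437 f + 1)} Hz.
#'
#' @param f frequency in Hz.
#' @param e ERB-rate value.
#' @export
erb_rate <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname erb_rate
#' @export
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' @rdname erb_rate
#' @export
erb_bandwidth <- function(f) 24.7 * (0.00437 * f + 1)

#' Design an ERB-spaced filterbank
#'
#' Places gammatone center frequencies at successive steps of `spacing`
#' ERB units starting at `f_min`, without exceeding `f_max`. The default
#' speech-analysis configuration (50-5000 Hz, 1 ERB) yields 28 channels.
#'
#' @param f_min,f_max frequency range in Hz.
#' @param spacing spacing between consecutive centers in ERB units.
#' @return an object of class `filterbank_spec` with the center frequencies.
#' @export
erb_space <- function(f_min = 50, f_max = 5000, spacing = 1) {
  check_scalar_number(f_min, "f_min", positive = TRUE)
  check_scalar_number(f_max, "f_max", positive = TRUE)
  check_scalar_number(spacing, "spacing", positive = TRUE)
  if (f_min > f_max) stop_invalid("`f_min` must not exceed `f_max`")
  e0 <- erb_rate(f_min)
  e1 <- erb_rate(f_max)
  n <- as.integer(floor((e1 - e0) / spacing + 1e-9)) + 1L
  cf <- erb_rate_inv(e0 + spacing * (seq_len(n) - 1L))
  cf[1] <- f_min # guard against round-trip rounding
  structure(
    list(f_min = f_min, f_max = f_max, spacing = spacing,
         n_channels = n, center_freqs = cf),
    class = "filterbank_spec")
}

#' @export
print.filterbank_spec <- function(x, ...) {
  cat(sprintf("ERB filterbank: %d channels, %.4g-%.4g Hz, %.3g ERB spacing\n",
              x$n_channels, x$f_min, x$f_max, x$spacing))
  invisible(x)
}

# Slaney's four cascaded second-order sections implementing the 4th-order
# all-pole gammatone approximation at center frequency cf.
gammatone_coefs <- function(cf, fs) {
  T <- 1 / fs
  B <- 1.019 * 2 * pi * erb_bandwidth(cf)
  w <- 2 * pi * cf * T
  cosw <- cos(w); sinw <- sin(w)
  eBT <- exp(B * T)
  a0 <- T
  a2 <- 0
  b0 <- 1
  b1 <- -2 * cosw / eBT
  b2 <- exp(-2 * B * T)
  sq_p <- sqrt(3 + 2^1.5)
  sq_m <- sqrt(3 - 2^1.5)
  a11 <- -(2 * T * cosw / eBT + 2 * sq_p * T * sinw / eBT) / 2
  a12 <- -(2 * T * cosw / eBT - 2 * sq_p * T * sinw / eBT) / 2
  a13 <- -(2 * T * cosw / eBT + 2 * sq_m * T * sinw / eBT) / 2
  a14 <- -(2 * T * cosw / eBT - 2 * sq_m * T * sinw / eBT) / 2
  ew <- exp(4i * pi * cf * T)
  ebw <- exp(-(B * T) + 2i * pi * cf * T)
  gain <- abs(
    (-2 * ew * T + 2 * ebw * T * (cosw - sq_m * sinw)) *
    (-2 * ew * T + 2 * ebw * T * (cosw + sq_m * sinw)) *
    (-2 * ew * T + 2 * ebw * T * (cosw - sq_p * sinw)) *
    (-2 * ew * T + 2 * ebw * T * (cosw + sq_p * sinw)) /
    (-2 / exp(2 * B * T) - 2 * ew + 2 * (1 + ew) / eBT)^4)
  list(a0 = a0, a2 = a2, b = c(b0, b1, b2),
       a1x = c(a11, a12, a13, a14), gain = gain)
}

# One subband of the gammatone filterbank, causal (forward-only) IIR.
gammatone_apply <- function(x, cf, fs) {
  co <- gammatone_coefs(cf, fs)
  y <- x
  for (k in 1:4) {
    num <- c(co$a0, co$a1x[k], co$a2)
    if (k == 1L) num <- num / co$gain
    xp <- c(0, 0, y)
    v <- stats::filter(xp, num, method = "convolution", sides = 1)
    v <- as.numeric(v)[-(1:2)]
    v[is.na(v)] <- 0
    y <- as.numeric(stats::filter(v, -co$b[2:3], method = "recursive"))
  }
  y
}

#' Decompose audio into gammatone subbands
#'
#' @param audio numeric waveform.
#' @param fs sampling rate in Hz.
#' @param spec an [erb_space()] filterbank specification.
#' @return samples x channels matrix of subband signals.
#' @export
gammatone_filterbank <- function(audio, fs, spec = erb_space()) {
  check_scalar_number(fs, "fs", positive = TRUE)
  if (anyNA(audio) || !all(is.finite(audio)))
    stop_invalid("`audio` contains NA or non-finite samples")
  if (fs <= 2 * spec$f_max)
    stop_invalid("`fs` must exceed twice the highest filterbank frequency")
  vapply(spec$center_freqs, function(cf) gammatone_apply(audio, cf, fs),
         numeric(length(audio)))
}

#' Extract the broadband speech envelope
#'
#' Filters the audio through an ERB-spaced gammatone filterbank, compresses
#' each subband sample-wise as \eqn{|x|^{exponent}}, and averages the
#' subband envelopes into a single non-negative envelope at the input rate.
#'
#' @param audio numeric waveform (mono).
#' @param fs sampling rate in Hz; must exceed twice `spec$f_max`.
#' @param spec an [erb_space()] filterbank specification.
#' @param exponent power-law compression exponent (default 0.6).
#' @return an [envelope_signal()] at the input rate.
#' @export
extract_envelope <- function(audio, fs, spec = erb_space(), exponent = 0.6) {
  sub <- gammatone_filterbank(audio, fs, spec)
  env <- rowMeans(abs(sub)^exponent)
  envelope_signal(env, fs)
}

#' Construct an envelope signal
#'
#' @param samples numeric vector of envelope amplitudes.
#' @param fs sampling rate in Hz.
#' @param band optional `(low, high)` Hz if the envelope has been band-passed.
#' @return object of class `envelope_signal`.
#' @export
envelope_signal <- function(samples, fs, band = NULL) {
  check_scalar_number(fs, "fs", positive = TRUE)
  structure(list(samples = as.numeric(samples), fs = fs, band = band),
            class = "envelope_signal")
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("envelope: %d samples @ %g Hz (%.2f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$band)) "" else
                sprintf(", band %g-%g Hz", x$band[1], x$band[2])))
  invisible(x)
}

#' @export
length.envelope_signal <- function(x) length(x$samples)
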