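# Zero-phase Chebyshev type-II band-pass filtering and polyphase resampling.
#
# The band-pass filter is designed in zero-pole-gain form and applied as a
# cascade of second-order sections: a 0.5-4 Hz passband at a 256 Hz rate
# needs a 24th-order digital filter whose expanded transfer-function
# polynomial is numerically unusable, while the biquad cascade is stable.

# Analog Chebyshev type-II low-pass prototype (stopband edge at 1 rad/s).
cheb2_prototype <- function(n, Rs) {
  eps <- 1 / sqrt(10^(Rs / 10) - 1)
  mu <- asinh(1 / eps) / n
  theta <- pi * (2 * seq_len(n) - 1) / (2 * n)
  p <- 1 / (-sinh(mu) * sin(theta) + 1i * cosh(mu) * cos(theta))
  keep <- abs(cos(theta)) > 1e-12 # odd order: drop the zero at infinity
  z <- 1i / cos(theta[keep])
  g <- Re(prod(-p) / prod(-z))
  list(zero = z, pole = p, gain = g)
}

# Minimum Chebyshev order for given passband/stopband edges (rad/s, analog).
cheb_min_order <- function(wp, ws, Rp, Rs) {
  # low-pass prototype selectivity for a band-pass specification
  sel_bp <- function(w, wp) abs((w^2 - wp[1] * wp[2]) / (w * (wp[2] - wp[1])))
  ws_sel <- min(sel_bp(ws[1], wp), sel_bp(ws[2], wp))
  num <- acosh(sqrt((10^(Rs / 10) - 1) / (10^(Rp / 10) - 1)))
  max(1L, as.integer(ceiling(num / acosh(ws_sel))))
}

# Pair conjugate roots into quadratic factors with real coefficients.
pair_conjugates <- function(v) {
  v <- v[order(round(Re(v), 9), round(abs(Im(v)), 9), sign(Im(v)))]
  used <- rep(FALSE, length(v))
  out <- list()
  for (i in seq_along(v)) {
    if (used[i]) next
    if (abs(Im(v[i])) < 1e-9) {
      j <- which(!used & seq_along(v) > i & abs(Im(v)) < 1e-9)[1]
      if (is.na(j)) {
        out[[length(out) + 1L]] <- v[i]
        used[i] <- TRUE
      } else {
        out[[length(out) + 1L]] <- c(v[i], v[j])
        used[c(i, j)] <- TRUE
      }
    } else {
      j <- which(!used & seq_along(v) != i & Mod(v - Conj(v[i])) < 1e-7)[1]
      if (is.na(j)) stop_invalid("unpaired complex root in filter design")
      out[[length(out) + 1L]] <- c(v[i], v[j])
      used[c(i, j)] <- TRUE
    }
  }
  out
}

# Convert zero-pole-gain to second-order sections (matrix with columns
# b0 b1 b2 a0 a1 a2), pairing each pole pair with the nearest zero pair.
zpk_to_sos <- function(zero, pole, gain) {
  zp <- pair_conjugates(zero)
  pp <- pair_conjugates(pole)
  if (length(zp) < length(pp)) {
    zp <- c(zp, replicate(length(pp) - length(zp), complex(0), simplify = FALSE))
  }
  pp <- pp[order(-vapply(pp, function(q) max(Mod(q)), 0))]
  zfreq <- vapply(zp, function(q) if (length(q)) abs(Arg(q[1])) else Inf, 0)
  zused <- rep(FALSE, length(zp))
  sos <- matrix(0, length(pp), 6L)
  for (i in seq_along(pp)) {
    pf <- abs(Arg(pp[[i]][1]))
    d <- ifelse(zused, Inf, abs(zfreq - pf))
    j <- which.min(d)
    zused[j] <- TRUE
    b <- Re(poly_from_roots(zp[[j]]))
    a <- Re(poly_from_roots(pp[[i]]))
    sos[i, ] <- c(c(b, rep(0, 3 - length(b))), c(a, rep(0, 3 - length(a))))
  }
  list(sos = sos, gain = gain)
}

poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Single-pass cascade filter; x may be a vector or a samples x series matrix.
sos_filter <- function(sosg, x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L)
  y <- sos_filter_cpp(x, sosg$sos, sosg$gain)
  if (vec) drop(y) else y
}

# Forward-backward (zero-phase) application with odd-reflection padding.
# The padding length follows the slowest pole's decay so that edge
# transients of narrow low-frequency designs die out inside the padding.
sos_filtfilt <- function(sosg, x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  npad <- min(n - 1L, max(9L * nrow(sosg$sos), sosg$npad %||% 0L))
  first <- x[rep(1L, npad), , drop = FALSE]
  last <- x[rep(n, npad), , drop = FALSE]
  pre <- 2 * first - x[(npad + 1L):2L, , drop = FALSE]
  post <- 2 * last - x[(n - 1L):(n - npad), , drop = FALSE]
  y <- sos_filter(sosg, rbind(pre, x, post))
  y <- sos_filter(sosg, y[nrow(y):1L, , drop = FALSE])
  y <- y[nrow(y):1L, , drop = FALSE][(npad + 1L):(npad + n), , drop = FALSE]
  if (vec) drop(y) else y
}

#' Design the zero-phase Chebyshev type-II band-pass filter
#'
#' Designs the band-pass filter used throughout the pipeline: stopband edges
#' 10\% outside the passband, with `atten_db` of stopband attenuation reached
#' by the combination of the forward and backward pass (each single pass is
#' designed for `atten_db / 2`).
#'
#' @param band numeric length-2, passband `(low, high)` in Hz.
#' @param fs sampling rate in Hz.
#' @param atten_db total two-pass stopband attenuation in dB (default 80).
#' @param transition relative width of the transition bands (default 0.1).
#' @return an object of class `bandpass_design` holding the second-order
#'   sections, the design edges and a magnitude-response function.
#' @export
design_bandpass <- function(band, fs, atten_db = 80, transition = 0.1) {
  check_scalar_number(fs, "fs", positive = TRUE)
  if (length(band) != 2L || !all(is.finite(band)) || band[1] <= 0 ||
      band[1] >= band[2] || band[2] >= fs / 2)
    stop_invalid("`band` must satisfy 0 < low < high < fs/2")
  stopband <- c(band[1] * (1 - transition), band[2] * (1 + transition))
  if (stopband[2] >= fs / 2)
    stop_invalid("upper stopband edge reaches the Nyquist frequency")
  rs_pass <- atten_db / 2
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  wp <- warp(band); ws <- warp(stopband)
  n <- cheb_min_order(wp, ws, Rp = 1, Rs = rs_pass)
  proto <- cheb2_prototype(n, rs_pass)
  zp <- signal::Zpg(zero = proto$zero, pole = proto$pole, gain = proto$gain)
  bp <- signal::sftrans(zp, W = ws, stop = FALSE)
  dz <- signal::bilinear(bp, T = 1 / fs)
  sosg <- zpk_to_sos(dz$zero, dz$pole, dz$gain)
  # padding horizon: three time constants of the slowest pole
  pmax_mod <- max(Mod(dz$pole))
  npad <- as.integer(ceiling(-3 / log(min(pmax_mod, 1 - 1e-12))))
  structure(
    list(sos = sosg$sos, gain = sosg$gain, band = band, stopband = stopband,
         fs = fs, order = n, atten_db = atten_db, npad = npad,
         zero = dz$zero, pole = dz$pole, zgain = dz$gain),
    class = "bandpass_design")
}

#' Magnitude response of a band-pass design
#'
#' @param design a [design_bandpass()] object.
#' @param freq frequencies in Hz.
#' @param passes 1 for a single pass, 2 for the zero-phase double pass.
#' @return magnitude (linear) at `freq`.
#' @export
bandpass_response <- function(design, freq, passes = 2) {
  w <- exp(2i * pi * freq / design$fs)
  h <- vapply(w, function(wi)
    abs(design$zgain * prod(wi - design$zero) / prod(wi - design$pole)), 0)
  h^passes
}

#' Zero-phase band-pass filter a signal or EEG recording
#'
#' Applies the same forward-backward Chebyshev type-II filter to a numeric
#' vector, an [envelope_signal()] or an [eeg_recording()]; the identical code
#' path guarantees that stimulus envelope and EEG receive the same filter.
#'
#' @param x numeric vector, `envelope_signal` or `eeg_recording`.
#' @param band passband `(low, high)` in Hz; the presets `"delta"` and
#'   `"theta"` map to 0.5-4 Hz and 4-8 Hz.
#' @param fs sampling rate; taken from the object when it carries one.
#' @param atten_db,transition see [design_bandpass()].
#' @return the filtered object, same type and shape as the input.
#' @export
bandpass <- function(x, band, fs = NULL, atten_db = 80, transition = 0.1) {
  band <- band_preset(band)
  if (inherits(x, "eeg_recording")) {
    d <- design_bandpass(band, x$fs, atten_db, transition)
    y <- t(sos_filtfilt(d, t(x$data)))
    out <- x
    out$data <- y
    out$band <- band
    return(out)
  }
  if (inherits(x, "envelope_signal")) {
    d <- design_bandpass(band, x$fs, atten_db, transition)
    out <- x
    out$samples <- sos_filtfilt(d, x$samples)
    out$band <- band
    return(out)
  }
  if (is.null(fs)) stop_invalid("`fs` is required for a plain numeric input")
  d <- design_bandpass(band, fs, atten_db, transition)
  sos_filtfilt(d, x)
}

#' @rdname bandpass
#' @export
band_preset <- function(band) {
  if (is.character(band)) {
    band <- match.arg(band, c("delta", "theta"))
    band <- switch(band, delta = c(0.5, 4), theta = c(4, 8))
  }
  band
}

# ---- resampling -------------------------------------------------------------

# Kaiser-windowed sinc low-pass for polyphase resampling; each polyphase
# branch is normalised to unit DC gain so constant signals are preserved
# exactly.
resample_kernel <- function(p, q, taps_per_branch = 10L, beta = 7) {
  m <- max(p, q)
  half <- taps_per_branch * m
  k <- (-half):half
  fc <- 1 / (2 * m)
  h <- 2 * fc * sinc(2 * fc * k) * kaiser_window(length(k), beta)
  h
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

kaiser_window <- function(n, beta) {
  k <- seq(0, n - 1)
  r <- 2 * k / (n - 1) - 1
  besselI(beta * sqrt(pmax(1 - r^2, 0)), 0) / besselI(beta, 0)
}

#' Anti-aliased polyphase resampling
#'
#' Resamples by the rational factor best approximating `fs_out / fs_in`
#' (upsample, windowed-sinc low-pass, downsample). Duration is preserved to
#' within one output sample; polyphase branches are DC-normalised so a
#' constant input yields the identical constant.
#'
#' @param x numeric vector, `envelope_signal` or `eeg_recording`.
#' @param fs_out target rate in Hz.
#' @param fs_in input rate; taken from the object when it carries one.
#' @return the resampled object, same type as the input.
#' @export
resample_to <- function(x, fs_out, fs_in = NULL) {
  check_scalar_number(fs_out, "fs_out", positive = TRUE)
  if (inherits(x, "eeg_recording")) {
    out <- x
    out$data <- t(resample_matrix(t(x$data), x$fs, fs_out))
    rownames(out$data) <- x$labels
    out$fs <- fs_out
    return(out)
  }
  if (inherits(x, "envelope_signal")) {
    out <- x
    out$samples <- resample_vector(x$samples, x$fs, fs_out)
    out$fs <- fs_out
    return(out)
  }
  if (is.null(fs_in)) stop_invalid("`fs_in` is required for a numeric vector")
  resample_vector(x, fs_in, fs_out)
}

resample_vector <- function(x, fs_in, fs_out) {
  drop(resample_matrix(matrix(x, ncol = 1L), fs_in, fs_out))
}

resample_matrix <- function(x, fs_in, fs_out) {
  if (fs_out > fs_in) stop_invalid("`fs_out` must not exceed the input rate")
  if (abs(fs_out - fs_in) < 1e-12) return(x)
  pq <- rational_ratio(fs_out / fs_in)
  p <- pq[["p"]]; q <- pq[["q"]]
  n <- nrow(x)
  n_out <- as.integer(ceiling(n * p / q))
  h <- resample_kernel(p, q)
  half <- (length(h) - 1L) %/% 2L
  # edge padding (replication) so transients do not bleed zeros inward
  npad <- as.integer(ceiling(half / p)) + q
  xp <- rbind(x[rep(1L, npad), , drop = FALSE], x,
              x[rep(n, npad), , drop = FALSE])
  if (p == 1L) {
    up <- xp
  } else {
    up <- matrix(0, nrow(xp) * p, ncol(x))
    up[seq(1L, nrow(up), by = p), ] <- xp
  }
  # zero-phase FIR: centred convolution (zero-padded boundaries fall inside
  # the replicated padding region)
  y <- fir_filter_cpp(up, h)
  # normalise each polyphase branch to unit DC gain
  phase_gain <- vapply(seq_len(p), function(ph)
    sum(h[seq(ph, length(h), by = p)]), 0)
  idx0 <- npad * p # offset of the true signal start in `up`
  out_idx <- idx0 + seq(0L, by = q, length.out = n_out)
  gain_idx <- ((out_idx + half) %% p) + 1L
  y[out_idx + 1L, , drop = FALSE] / phase_gain[gain_idx]
}
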