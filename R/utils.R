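# Small shared helpers: argument checking, z-scoring, rational rate ratios.

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_invalid(sprintf("`%s` must be > 0", name))
  invisible(x)
}

# Column z-score; constant columns are left at zero rather than NaN.
zscore <- function(x) {
  if (is.matrix(x)) {
    mu <- colMeans(x)
    s <- sqrt(pmax(colMeans(x^2) - mu^2, 0))
    s[s < .Machine$double.eps] <- 1
    scale(x, center = mu, scale = s)[, , drop = FALSE]
  } else {
    mu <- mean(x)
    s <- sqrt(max(mean(x^2) - mu^2, 0))
    if (!is.finite(s) || s < .Machine$double.eps) s <- 1
    (x - mu) / s
  }
}

# Best rational approximation p/q of a positive ratio (continued fractions),
# used to express a resampling ratio fs_out/fs_in exactly.
rational_ratio <- function(ratio, max_den = 1024L) {
  stopifnot(is.finite(ratio), ratio > 0)
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  x <- ratio
  repeat {
    a <- floor(x)
    p2 <- as.integer(a * p1 + p0); q2 <- as.integer(a * q1 + q0)
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - ratio) < 1e-12) break
    frac <- x - a
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  c(p = max(p1, 1L), q = max(q1, 1L))
}

# Deterministic sub-seed derivation; keeps values well inside 32-bit range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i * 12345) %% 2147483587
  as.integer(s)
}

ms_to_samples <- function(ms, fs) as.integer(round(ms / 1000 * fs))

`%||%` <- function(a, b) if (is.null(a)) b else a
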