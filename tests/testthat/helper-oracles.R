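# Independent oracles used across the test files.

# Brute-force ridge normal equations in the decoder orientation: channels are
# z-scored, lagged with zero padding, and the system
# (R R^T + lambda I) g = R S^T is solved directly.
oracle_backward <- function(eeg_data, env, lags, lambda = NULL) {
  C <- nrow(eeg_data)
  n <- ncol(eeg_data)
  zrow <- function(x) {
    mu <- mean(x)
    s <- sqrt(max(mean(x^2) - mu^2, 0))
    (x - mu) / max(s, .Machine$double.eps)
  }
  zd <- t(apply(eeg_data, 1, zrow))
  D <- matrix(0, n, C * length(lags))
  for (ci in seq_len(C)) {
    for (k in seq_along(lags)) {
      tau <- lags[k]
      D[1:(n - tau), (ci - 1) * length(lags) + k] <- zd[ci, (1 + tau):n]
    }
  }
  G <- crossprod(D)
  if (is.null(lambda)) lambda <- max(abs(G))
  sv <- zrow(env)
  w <- solve(G + lambda * diag(ncol(D)), crossprod(D, sv))
  list(w = as.numeric(w), lambda = lambda, design = D, target = sv)
}

# Forward-model oracle: EEG channel regressed on the delayed envelope.
oracle_forward <- function(eeg_data, env, lags, lambda) {
  n <- length(env)
  zrow <- function(x) {
    mu <- mean(x)
    s <- sqrt(max(mean(x^2) - mu^2, 0))
    (x - mu) / max(s, .Machine$double.eps)
  }
  sz <- zrow(env)
  D <- matrix(0, n, length(lags))
  for (k in seq_along(lags)) {
    tau <- lags[k]
    D[(1 + tau):n, k] <- sz[1:(n - tau)]
  }
  G <- crossprod(D) + lambda * diag(ncol(D))
  Y <- apply(eeg_data, 1, zrow) # n x C
  t(solve(G, crossprod(D, Y))) # C x lags
}

# Exact 1-D k-means by dynamic programming (O(n^2 k)); returns the minimal
# within-cluster sum of squares for sorted input.
oracle_kmeans_1d <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  sse <- function(i, j) { # within-SS of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  for (j in 1:n) dp[1, j] <- sse(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf
        for (i in m:j) {
          v <- dp[m - 1, i - 1] + sse(i, j)
          if (v < best) best <- v
        }
        dp[m, j] <- best
      }
    }
  }
  dp[k, n]
}

# k-means objective realized by a label assignment.
kmeans_objective <- function(x, labels) {
  sum(unlist(lapply(split(x, labels), function(g) sum((g - mean(g))^2))))
}

# Small deterministic EEG fixture: sinusoidal channels (bounded, so the MWF
# detector finds nothing unless artifacts are injected).
sine_eeg <- function(C = 8, n = 1024, fs = 128) {
  tt <- seq_len(n) / fs
  data <- t(vapply(seq_len(C), function(ci)
    10 * sin(2 * pi * (ci + 0.5) * tt + ci), numeric(n)))
  eeg_recording(data, fs)
}

read_behavioral_fixture <- function() {
  jsonlite::read_json(system.file("extdata", "behavioral.json",
                                  package = "envtrack"),
                      simplifyVector = TRUE)
}
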