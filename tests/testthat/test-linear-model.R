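test_that("the lagged design follows the advance-lag convention", {
  # 1 channel [1,2,3], lags {0, +1 sample}
  lm1 <- lag_matrix(matrix(c(1, 2, 3), 1), lag_spec(0, 1100, 1))
  expect_equal(lm1, matrix(c(1, 2, 3, 2, 3, 0), 3, 2))
  # lags {0} reproduces the transposed data
  x <- matrix(rnorm(20), 2)
  expect_equal(lag_matrix(x, lag_spec(0, 900, 1)), t(x))
  # the full-size configuration spans 64 x 65 columns
  ls <- lag_spec(0, 500, 128)
  expect_equal(ls$n_lags, 65L)
  expect_equal(ncol(lag_matrix(matrix(0, 64, 200), ls)), 4160L)
  expect_error(lag_matrix(matrix(0, 2, 10), lag_spec(0, 500, 128)),
               "longer than")
})

test_that("an identity system is decoded exactly", {
  fs <- 64
  set.seed(8)
  s <- as.numeric(bandpass(rnorm(fs * 30), c(0.5, 4), fs = fs))
  eeg <- eeg_recording(rbind(s, rnorm(length(s))), fs)
  dec <- train_backward(eeg, envelope_signal(s, fs),
                        lag_spec(0, 1000 / fs * 0.9, fs), lambda = 1e-8)
  expect_gt(abs(dec$weights[1, 1]), 10 * max(abs(dec$weights[2, ])))
  rho <- cor(reconstruct(dec, eeg)$samples, s, method = "spearman")
  expect_gt(rho, 0.999)
})

test_that("decoder and TRF match brute-force normal equations", {
  set.seed(2)
  C <- 8
  n <- 1500
  X <- matrix(rnorm(C * n), C)
  env <- rnorm(n)
  fs <- 32
  lsX <- lag_spec(0, 220, fs)
  eegX <- eeg_recording(X, fs)
  envX <- envelope_signal(env, fs)
  # default lambda rule
  dec <- train_backward(eegX, envX, lsX)
  orc <- oracle_backward(X, env, lsX$lags)
  expect_equal(dec$lambda, orc$lambda)
  expect_lt(max(abs(as.vector(t(dec$weights)) - orc$w)) / max(abs(orc$w)),
            1e-6)
  # explicit lambda
  dec2 <- train_backward(eegX, envX, lsX, lambda = 3.7)
  orc2 <- oracle_backward(X, env, lsX$lags, lambda = 3.7)
  expect_lt(max(abs(as.vector(t(dec2$weights)) - orc2$w)) / max(abs(orc2$w)),
            1e-6)
  # reconstruction equals the design-matrix product
  sh <- reconstruct(dec, eegX)
  expect_lt(max(abs(sh$samples - as.numeric(orc$design %*% orc$w))), 1e-9)
  # forward model against its own oracle
  trf <- train_forward(envX, eegX, lsX, lambda = 2.5)
  ko <- oracle_forward(X, env, lsX$lags, lambda = 2.5)
  expect_lt(max(abs(trf$kernel - ko)) / max(abs(ko)), 1e-6)
  # rank-deficient design with a zero ridge is refused
  dup <- eeg_recording(rbind(X[1, ], X[1, ]), fs)
  expect_error(train_backward(dup, envX, lsX, lambda = 0),
               "rank deficient")
})

test_that("reconstruction is linear in the decoder weights", {
  set.seed(3)
  eeg <- eeg_recording(matrix(rnorm(4 * 400), 4), 32)
  env <- envelope_signal(rnorm(400), 32)
  dec <- train_backward(eeg, env, lag_spec(0, 120, 32))
  dec0 <- dec
  dec0$weights[] <- 0
  expect_true(all(reconstruct(dec0, eeg)$samples == 0))
  dec3 <- dec
  dec3$weights <- 3 * dec$weights
  expect_equal(reconstruct(dec3, eeg)$samples,
               3 * reconstruct(dec, eeg)$samples, tolerance = 1e-12)
})

test_that("noiseless synthetic EEG is decoded and identified accurately", {
  fs <- 128
  tl <- gen_matrix_timeline(2, 20, seed = 5)
  env <- gen_envelope(tl, fs = fs, seed = 6)
  K <- reference_kernel("attention", fs = fs)
  eegK <- gen_eeg(env, K, gain = 1, noise_cfg = list(rms = 0),
                  artifact_cfg = list(blink_rate = 0), seed = 7)
  ls <- lag_spec(0, 500, fs)
  dec <- train_backward(eegK, env, ls, lambda = 1)
  rho <- cor(reconstruct(dec, eegK)$samples, env$samples)
  expect_gt(rho, 0.99)
  # forward system identification recovers every channel kernel
  trf <- train_forward(env, eegK, ls)
  nl <- min(ncol(trf$kernel), ncol(K$kernel))
  cors <- vapply(seq_len(64), function(ci)
    cor(trf$kernel[ci, 1:nl], K$kernel[ci, 1:nl]), 0)
  expect_gt(min(cors), 0.95)
  # the TRF of attended synthetic speech has the +/-/+ morphology
  pk <- trf_peaks(trf)
  expect_gt(pk$amplitude[pk$label == "P1"], 0)
  expect_lt(pk$amplitude[pk$label == "N1"], 0)
  expect_gt(pk$amplitude[pk$label == "P2"], 0)
  # all-zero EEG gives an all-zero TRF
  zero <- eeg_recording(matrix(0, 64, length(env$samples)), fs,
                        labels = biosemi64_labels())
  expect_true(all(train_forward(env, zero, ls)$kernel == 0))
})

test_that("training-set correlation is non-increasing along the ridge path", {
  set.seed(9)
  fs <- 64
  eeg <- eeg_recording(matrix(rnorm(16 * 2000), 16), fs)
  env <- envelope_signal(as.numeric(bandpass(rnorm(2000), c(0.5, 4),
                                             fs = fs)), fs)
  ls <- lag_spec(0, 150, fs)
  rhos <- vapply(c(0.1, 1, 10, 100, 1e3, 1e4), function(l) {
    dec <- train_backward(eeg, env, ls, lambda = l)
    cor(reconstruct(dec, eeg)$samples, env$samples)
  }, 0)
  expect_true(all(diff(rhos) <= 1e-9))
})

test_that("time reversal leaves the instantaneous decoder unchanged", {
  set.seed(10)
  fs <- 64
  x <- matrix(rnorm(4 * 600), 4)
  env <- rnorm(600)
  ls0 <- lag_spec(0, 900 / fs, fs) # single lag at 0
  d1 <- train_backward(eeg_recording(x, fs), envelope_signal(env, fs), ls0)
  r1 <- cor(reconstruct(d1, eeg_recording(x, fs))$samples, env)
  xr <- x[, ncol(x):1]
  d2 <- train_backward(eeg_recording(xr, fs),
                       envelope_signal(rev(env), fs), ls0)
  r2 <- cor(reconstruct(d2, eeg_recording(xr, fs))$samples, rev(env))
  expect_equal(abs(r1), abs(r2), tolerance = 1e-9)
})

test_that("trf_peaks searches the configured windows", {
  K <- reference_kernel("attention", fs = 128)
  pk <- trf_peaks(K, interpolate = FALSE)
  expect_equal(pk$latency_ms, c(46.875, 78.125, 156.25))
  pk_i <- trf_peaks(K)
  expect_equal(pk_i$latency_ms, c(50, 80, 160), tolerance = 1.5)
  # single positive bump at 100 ms: the N1 window returns its flank minimum
  lag_ms <- seq(0, 400, length.out = 52)
  bump <- structure(list(kernel = matrix(exp(-((lag_ms - 100) / 15)^2), 1,
                                         dimnames = list("Cz", NULL)),
                         lag_ms = lag_ms),
                    class = "forward_trf")
  pkb <- trf_peaks(bump, windows = list(N1 = c(60, 120)),
                   interpolate = FALSE)
  expect_equal(pkb$latency_ms, lag_ms[which(lag_ms >= 60)[1]])
  expect_error(trf_peaks(K, windows = list(P9 = c(900, 950))), "no lags")
  expect_error(trf_peaks(K, channels = "NOPE"), "unknown channel")
})

test_that("bootstrapped Spearman scores behave like a rank statistic", {
  set.seed(11)
  a <- rnorm(4000)
  # any strictly monotone transform has rho exactly 1
  sc <- bootstrap_spearman(a, exp(a), n_boot = 200, seed = 1,
                           block_len = 200)
  expect_equal(sc$rho_median, 1)
  expect_true(sc$ci_low <= sc$rho_median && sc$rho_median <= sc$ci_high)
  # independent noise: small median, interval covers zero
  b <- rnorm(1e4)
  sc0 <- bootstrap_spearman(rnorm(1e4), b, n_boot = 400, seed = 2,
                            block_len = 100)
  expect_lt(abs(sc0$rho_median), 0.05)
  # the interval sits at zero up to the O(1/sqrt(n)) sampling error
  expect_lt(sc0$ci_low, 0.05)
  expect_gt(sc0$ci_high, -0.05)
  # deterministic under seed
  b2 <- exp(a) + rnorm(4000)
  sc1 <- bootstrap_spearman(a, b2, n_boot = 100, seed = 3)
  sc2 <- bootstrap_spearman(a, b2, n_boot = 100, seed = 3)
  expect_identical(sc1$rho_median, sc2$rho_median)
  expect_error(bootstrap_spearman(rep(1, 100), rnorm(100)), "constant")
  expect_error(bootstrap_spearman(rnorm(10), rnorm(11)), "equal length")
})
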