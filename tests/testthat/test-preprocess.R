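test_that("blanking interpolates only supra-threshold samples", {
  e <- eeg_recording(matrix(c(0, 600, 0, 1, 2, 3), 2, 3, byrow = TRUE), 10)
  b <- blank_and_interpolate(e, 500)
  expect_equal(unname(b$data[1, ]), c(0, 0, 0))
  expect_identical(b$data[2, ], e$data[2, ]) # untouched channel bit-identical
  # a run of k supra-threshold samples becomes an arithmetic progression
  x <- c(2, 700, 900, -800, 10)
  run <- blank_and_interpolate(eeg_recording(matrix(x, 1), 10))$data[1, ]
  expect_equal(unname(run), c(2, 4, 6, 8, 10))
  # sub-threshold recordings pass through bit-identically
  ok <- eeg_recording(matrix(rnorm(200, sd = 50), 4), 10)
  expect_identical(blank_and_interpolate(ok)$data, ok$data)
  # edge runs hold the nearest surviving value
  edge <- blank_and_interpolate(eeg_recording(matrix(c(900, 700, 5, 3), 1),
                                              10))$data[1, ]
  expect_equal(unname(edge), c(5, 5, 5, 3))
  expect_error(blank_and_interpolate(eeg_recording(matrix(rep(600, 4), 1),
                                                   10)),
               "nothing to interpolate")
})

test_that("average re-referencing is an idempotent projection", {
  set.seed(1)
  e <- eeg_recording(matrix(rnorm(64 * 200), 64), 128)
  r1 <- rereference_average(e)
  expect_lt(max(abs(colMeans(r1$data))), 1e-9)
  expect_equal(r1$reference, "average")
  r2 <- rereference_average(r1)
  expect_lt(max(abs(r1$data - r2$data)), 1e-9)
  # identical constant on all channels vanishes
  cst <- eeg_recording(matrix(7, 8, 50), 128)
  expect_true(all(abs(rereference_average(cst)$data) < 1e-12))
})

test_that("the band-pass is zero-phase with the designed stopband", {
  fs <- 256
  d <- design_bandpass(c(0.5, 4), fs)
  # design magnitude response: >= 80 dB total attenuation at the stopband
  # edges and beyond, passband flat
  stop_frq <- c(0.45, 4.4, 6, 8, 20)
  expect_true(all(20 * log10(bandpass_response(d, stop_frq, passes = 2)) <=
                    -80 + 1e-6))
  expect_true(all(abs(20 * log10(bandpass_response(d, c(1, 2, 3),
                                                   passes = 2))) < 1))
  tt <- seq(0, 60, by = 1 / fs)
  mid <- 4000:11000
  y2 <- bandpass(sin(2 * pi * 2 * tt), "delta", fs = fs)
  expect_equal(max(abs(y2[mid])), 1, tolerance = 0.05)
  # zero phase: cross-correlation peak at lag 0
  cc <- ccf(y2[mid], sin(2 * pi * 2 * tt)[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # realized attenuation of an 8 Hz tone (transient-limited in time domain)
  y8 <- bandpass(sin(2 * pi * 8 * tt), c(0.5, 4), fs = fs)
  expect_lt(20 * log10(max(abs(y8[mid]))), -55)
  # a symmetric pulse stays symmetric about its center (odd length so that
  # reversal maps the center sample onto itself; the signal is long enough
  # that the filter's slow ringing dies out inside the recording)
  pulse <- exp(-((seq_len(16385) - 8193) / 40)^2)
  yp <- bandpass(pulse, c(0.5, 4), fs = fs)
  expect_lt(max(abs(yp - rev(yp))) / max(abs(yp)), 1e-5)
  expect_error(bandpass(rnorm(100), c(4, 200), fs = fs), "fs/2")
  expect_error(bandpass(rnorm(100), c(0, 4), fs = fs), "0 < low")
})

test_that("EEG and envelope go through the identical filter path", {
  fs <- 128
  set.seed(2)
  x <- rnorm(fs * 10)
  as_eeg <- bandpass(eeg_recording(matrix(x, 1), fs), "delta")
  as_env <- bandpass(envelope_signal(x, fs), "delta")
  as_vec <- bandpass(x, "delta", fs = fs)
  expect_identical(unname(as_eeg$data[1, ]), as_env$samples)
  expect_identical(as_env$samples, as_vec)
  expect_equal(band_preset("delta"), c(0.5, 4))
  expect_equal(band_preset("theta"), c(4, 8))
})

test_that("polyphase resampling preserves constants, tones and duration", {
  expect_equal(resample_to(rep(3.5, 1000), 128, fs_in = 256),
               rep(3.5, 500), tolerance = 1e-12)
  fs <- 256
  tt <- seq(0, 20, by = 1 / fs)
  y <- resample_to(sin(2 * pi * 10 * tt), 128, fs_in = fs)
  expect_equal(length(y), ceiling(length(tt) / 2))
  expect_equal(max(abs(y[300:2200])), 1, tolerance = 0.01)
  # awkward rational ratio
  x5 <- sin(2 * pi * 5 * seq(0, 10, by = 1 / 441))
  y5 <- resample_to(x5, 256, fs_in = 441)
  expect_equal(length(y5), ceiling(length(x5) * 256 / 441))
  expect_equal(max(abs(y5[300:2200])), 1, tolerance = 0.01)
  expect_error(resample_to(rnorm(100), -5, fs_in = 100), "> 0")
  expect_error(resample_to(rnorm(100), 200, fs_in = 100), "exceed")
})

test_that("the artifact mask flags power bursts on frontal channels", {
  fs <- 128
  e <- sine_eeg(C = 64, n = 4096, fs = fs)
  e$data <- e$data / 10 # unit-amplitude sines: crest factor 2 < 5, no mask
  expect_warning(res <- mwf_denoise(e), "no artifact")
  expect_identical(res$eeg$data, e$data)
  expect_false(any(res$mask))
  # one 10x burst on a frontal channel is flagged, the rest is not
  set.seed(3)
  noise <- matrix(rnorm(64 * 4096, sd = 1), 64,
                  dimnames = list(biosemi64_labels(), NULL))
  burst <- 1500:1530
  noise["Fp1", burst] <- noise["Fp1", burst] * 10
  eb <- eeg_recording(noise, fs)
  resb <- suppressWarnings(mwf_denoise(eb))
  # every burst sample whose amplitude is actually large is flagged
  big <- burst[abs(noise["Fp1", burst]) > 4]
  expect_true(all(resb$mask[big]))
  expect_gt(mean(resb$mask[burst]), 0.5)
  # Gaussian noise itself triggers the 5x power detector on ~2.5% of
  # samples per frontal channel; the burst must stand far above that rate
  expect_lt(mean(resb$mask[-burst]), 0.25)
  expect_error(mwf_denoise(e, frontal = c("Fp1", "NOPE")), "subset")
})

test_that("the multichannel Wiener filter removes synthetic blinks while
           preserving the brain signal", {
  fs <- 256
  tl <- gen_matrix_timeline(2, 20, seed = 11)
  env <- gen_envelope(tl, fs = fs, seed = 12)
  K <- reference_kernel("attention", fs = fs)
  clean <- gen_eeg(env, K, gain = 1, noise_cfg = list(rms = 10),
                   artifact_cfg = list(blink_rate = 0), seed = 13)
  # rank-1 frontal blink component with known ground truth
  set.seed(77)
  pulse <- envtrack:::blink_pulse(fs)
  topo <- envtrack:::scalp_map("Fpz", 4)[clean$labels]
  onsets <- sort(sample.int(ncol(clean$data) - length(pulse), 12))
  bl <- numeric(ncol(clean$data))
  for (on in onsets) {
    idx <- on:(on + length(pulse) - 1)
    bl[idx] <- bl[idx] + pulse
  }
  dirty <- clean
  dirty$data <- clean$data + 150 * outer(topo, bl)
  res <- mwf_denoise(dirty)
  blink_band <- function(x) as.numeric(bandpass(x, c(0.5, 2), fs = fs))
  p_blink <- mean(blink_band(dirty$data["Fp1", ] - clean$data["Fp1", ])^2)
  p_resid <- mean(blink_band(res$eeg$data["Fp1", ] -
                               clean$data["Fp1", ])^2)
  expect_gt(1 - p_resid / p_blink, 0.9) # >= 90% blink-band power removed
  cors <- vapply(seq_len(64), function(ci)
    cor(res$eeg$data[ci, ], clean$data[ci, ]), 0)
  expect_gt(median(cors), 0.95)
  # channels away from the ocular focus are only mildly affected; the
  # blink-dominated frontal row bears the unavoidable MMSE trade-off
  far <- topo < 0.05
  expect_gt(min(cors[far]), 0.9)
})
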