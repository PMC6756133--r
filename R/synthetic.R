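# Synthetic study generator: sentence timelines, modulated envelopes,
# condition-specific multichannel response kernels, behavioral word scores
# and envelope-driven EEG with known ground truth.

#' Generate a matrix-sentence stimulus timeline
#'
#' Concatenates `n_lists * sentences_per_list` sentences of
#' `sentence_duration` seconds separated by gaps drawn uniformly from
#' `gap_bounds`. The default two-list, 20-sentence configuration gives
#' exactly 80 s of speech in roughly 120 s.
#'
#' @param n_lists number of sentence lists (default 2).
#' @param sentences_per_list sentences per list (default 20).
#' @param gap_bounds `(min, max)` inter-sentence gap in seconds
#'   (default `c(0.8, 1.2)`).
#' @param seed integer seed.
#' @param sentence_duration sentence length in seconds (default 2).
#' @return object of class `stimulus_timeline` with `sentence_onsets`,
#'   `total_duration` and `n_sentences`.
#' @export
gen_matrix_timeline <- function(n_lists = 2L, sentences_per_list = 20L,
                                gap_bounds = c(0.8, 1.2), seed = 1L,
                                sentence_duration = 2) {
  if (n_lists < 1L || sentences_per_list < 1L)
    stop_invalid("counts must be at least 1")
  if (gap_bounds[1] > gap_bounds[2] || gap_bounds[1] < 0)
    stop_invalid("`gap_bounds` must satisfy 0 <= min <= max")
  n <- as.integer(n_lists) * as.integer(sentences_per_list)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  gaps <- if (n > 1L) runif(n - 1L, gap_bounds[1], gap_bounds[2]) else numeric(0)
  onsets <- cumsum(c(0, sentence_duration + gaps))
  structure(list(sentence_onsets = onsets,
                 sentence_duration = sentence_duration,
                 gap_bounds = gap_bounds,
                 total_duration = onsets[n] + sentence_duration,
                 n_sentences = n),
            class = "stimulus_timeline")
}

#' @export
print.stimulus_timeline <- function(x, ...) {
  cat(sprintf("timeline: %d sentences x %g s (%g s speech in %.2f s total)\n",
              x$n_sentences, x$sentence_duration,
              x$n_sentences * x$sentence_duration, x$total_duration))
  invisible(x)
}

#' Generate a synthetic speech envelope from a timeline
#'
#' Inside each sentence the envelope is a rectified sum of sinusoidal
#' modulators at the word and syllable rates riding on a DC pedestal; gaps
#' are exactly zero. Sentence-level amplitude jitter (seeded) mimics level
#' variation across sentences.
#'
#' @param timeline a [gen_matrix_timeline()] object.
#' @param fs sampling rate in Hz (>= 64).
#' @param mod_rates modulation rates in Hz (default word 2.5, syllable 4.1).
#' @param seed integer seed.
#' @return an [envelope_signal()] covering the full timeline.
#' @export
gen_envelope <- function(timeline, fs = 256, mod_rates = c(2.5, 4.1),
                         seed = 1L) {
  check_scalar_number(fs, "fs", positive = TRUE)
  if (fs < 64) stop_invalid("`fs` must be at least 64 Hz")
  if (fs < 2 * max(mod_rates))
    stop_invalid("`fs` below twice the highest modulation rate")
  n <- as.integer(ceiling(timeline$total_duration * fs))
  env <- numeric(n)
  if (timeline$n_sentences == 0L) return(envelope_signal(env, fs))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  jit <- runif(timeline$n_sentences, 0.9, 1.1)
  for (si in seq_len(timeline$n_sentences)) {
    on <- timeline$sentence_onsets[si]
    i0 <- as.integer(floor(on * fs)) + 1L
    i1 <- min(n, as.integer(floor((on + timeline$sentence_duration) * fs)))
    tt <- (seq(i0, i1) - 1) / fs - on
    env[i0:i1] <- jit[si] * pmax(
      0, 1 + 0.5 * sin(2 * pi * mod_rates[1] * tt) +
        0.5 * sin(2 * pi * mod_rates[2] * tt))
  }
  envelope_signal(env, fs)
}

# Gaussian bump over lag axis (ms)
lag_bump <- function(lag_ms, center_ms, sd_ms = 12) {
  exp(-0.5 * ((lag_ms - center_ms) / sd_ms)^2)
}

# Smooth scalp weight map centred on a template electrode.
scalp_map <- function(center_label, sigma_cm = 5,
                      positions = biosemi64_positions()) {
  p0 <- unlist(positions[positions$label == center_label, c("x", "y", "z")])
  d2 <- (positions$x - p0[1])^2 + (positions$y - p0[2])^2 +
    (positions$z - p0[3])^2
  w <- exp(-d2 / (2 * sigma_cm^2))
  setNames(w, positions$label)
}

#' Condition-specific reference response kernel
#'
#' A 64-channel kernel over post-stimulus lags built from three Gaussian
#' deflections: P1 (+, 50 ms), N1 (-, 80 ms) and P2 (+, 160 ms), each with
#' its own scalp topography. P1/N1 are fronto-central; the P2 topography has
#' a pronounced right-frontal component. In the `movie` condition the P2
#' amplitude is scaled by 0.4, so the attention-movie kernel difference is
#' a 160 ms deflection maximal over right-frontal channels.
#'
#' @param condition `"attention"` or `"movie"`.
#' @param fs sampling rate realizing the lag axis (default 128).
#' @param max_lag_ms kernel support in ms (default 400).
#' @param amplitude_uv overall scale in microvolts per envelope z-unit
#'   (default 0.8, chosen so that the default study's quiet-condition
#'   tracking correlations fall in the range reported for delta-band
#'   speech tracking).
#' @return object of class `reference_kernel` with `kernel`
#'   (channels x lags), `lag_ms`, `condition` and `peak_spec`.
#' @export
reference_kernel <- function(condition = c("attention", "movie"), fs = 128,
                             max_lag_ms = 400, amplitude_uv = 0.8) {
  condition <- match.arg(condition)
  lag_ms <- seq(0, floor(max_lag_ms / 1000 * fs)) / fs * 1000
  pos <- biosemi64_positions()
  central <- scalp_map("FCz", 5, pos)
  right_frontal <- scalp_map("F4", 4, pos)
  p2_scale <- if (condition == "movie") 0.4 else 1
  peaks <- list(
    list(label = "P1", latency_ms = 50, sign = 1, rel_amp = 0.6,
         map = central),
    list(label = "N1", latency_ms = 80, sign = -1, rel_amp = 1.0,
         map = central),
    list(label = "P2", latency_ms = 160, sign = 1,
         rel_amp = 1.0 * p2_scale,
         map = 0.4 * central + right_frontal))
  K <- matrix(0, nrow(pos), length(lag_ms), dimnames = list(pos$label, NULL))
  for (pk in peaks) {
    K <- K + amplitude_uv * pk$sign * pk$rel_amp *
      outer(pk$map, lag_bump(lag_ms, pk$latency_ms))
  }
  structure(list(kernel = K, lag_ms = lag_ms, fs = fs,
                 condition = condition, peak_spec = peaks),
            class = c("reference_kernel", "forward_trf"))
}

# 1/f^alpha Gaussian noise via spectral shaping, scaled to a target RMS;
# generates `k` independent series as columns.
pink_noise <- function(n, fs, rms = 20, exponent = 1, k = 1L) {
  if (rms <= 0) return(matrix(0, n, k))
  m <- nextn(n, 2)
  f <- c(1, seq_len(m / 2), seq(m / 2 - 1, 1)) # DC guarded
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  w <- matrix(rnorm(m * k), m, k)
  x <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / m
  x <- x[seq_len(n), , drop = FALSE]
  sweep(x, 2L, sqrt(colMeans(x^2)) / rms, `/`)
}

# Raised-cosine blink pulse
blink_pulse <- function(fs, dur_s = 0.3) {
  n <- max(3L, as.integer(round(dur_s * fs)))
  0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
}

#' Generate envelope-driven synthetic EEG
#'
#' EEG = `gain` x (kernel convolved with the z-scored envelope) per channel,
#' plus 1/f background noise, frontally weighted blink artifacts and
#' optional high-amplitude single-sample glitches.
#'
#' @param envelope an [envelope_signal()].
#' @param kernel a [reference_kernel()] whose lag axis is realized at the
#'   envelope rate.
#' @param gain tracking gain in `[0, 1]`.
#' @param noise_cfg list with `rms` (microvolts, default 20) and `exponent`
#'   (spectral slope, default 1).
#' @param artifact_cfg list with `blink_rate` (per minute, default 12),
#'   `blink_amp` (microvolts, default 150), `glitch_rate` (per minute,
#'   default 0) and `glitch_amp` (microvolts, default 800).
#' @param seed integer seed.
#' @return an [eeg_recording()] at the envelope rate.
#' @export
gen_eeg <- function(envelope, kernel, gain = 1,
                    noise_cfg = list(), artifact_cfg = list(), seed = 1L) {
  if (gain < 0 || gain > 1) stop_invalid("`gain` must lie in [0, 1]")
  if (abs(envelope$fs - kernel$fs) > 1e-9)
    stop_invalid("kernel lag axis and envelope rate differ")
  noise <- modifyList(list(rms = 20, exponent = 1), noise_cfg)
  art <- modifyList(list(blink_rate = 12, blink_amp = 150,
                         glitch_rate = 0, glitch_amp = 800), artifact_cfg)
  fs <- envelope$fs
  n <- length(envelope$samples)
  C <- nrow(kernel$kernel)
  labels <- rownames(kernel$kernel)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  s <- zscore(envelope$samples)
  x <- matrix(0, C, n, dimnames = list(labels, NULL))
  if (gain > 0) {
    # causal FIR convolution of the envelope with each channel kernel,
    # expressed as one kernel x lagged-envelope product
    nk <- ncol(kernel$kernel)
    E <- matrix(0, nk, n)
    for (k in seq_len(nk)) E[k, k:n] <- s[1:(n - k + 1L)]
    x <- gain * (kernel$kernel %*% E)
  }
  if (noise$rms > 0) {
    x <- x + t(pink_noise(n, fs, noise$rms, noise$exponent, k = C))
  }
  if (art$blink_rate > 0 && art$blink_amp > 0) {
    n_blinks <- rpois(1, art$blink_rate * n / fs / 60)
    if (n_blinks > 0) {
      pulse <- blink_pulse(fs)
      topo <- scalp_map("Fpz", 4)[labels]
      onsets <- sort(sample.int(max(1L, n - length(pulse)), n_blinks,
                                replace = TRUE))
      bl <- numeric(n)
      for (on in onsets) {
        idx <- on:(on + length(pulse) - 1L)
        bl[idx] <- bl[idx] + pulse
      }
      x <- x + art$blink_amp * outer(topo, bl)
    }
  }
  if (art$glitch_rate > 0 && art$glitch_amp > 0) {
    n_glitch <- rpois(1, art$glitch_rate * n / fs / 60)
    if (n_glitch > 0) {
      for (g in seq_len(n_glitch)) {
        ch <- sample.int(C, 1L)
        at <- sample.int(n, 1L)
        x[ch, at] <- x[ch, at] + sample(c(-1, 1), 1L) * art$glitch_amp
      }
    }
  }
  eeg_recording(x, fs, labels = labels)
}

#' Simulate behavioral word scores
#'
#' Draws per-SNR binomial word scores from the logistic psychometric
#' function with midpoint `alpha` and spread `beta`.
#'
#' @param alpha SRT in dB SNR.
#' @param beta spread in dB (> 0).
#' @param snrs SNRs in dB at which lists are presented.
#' @param n_words words per SNR (default 40).
#' @param seed integer seed.
#' @return data.frame with `snr`, `n_words`, `n_correct`, `proportion`.
#' @export
gen_behavioral_scores <- function(alpha, beta, snrs, n_words = 40L,
                                  seed = 1L) {
  if (beta <= 0) stop_invalid("`beta` must be > 0")
  if (n_words < 1L) stop_invalid("`n_words` must be at least 1")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  p <- psychometric_fun(snrs, alpha, beta)
  k <- rbinom(length(snrs), n_words, p)
  data.frame(snr = snrs, n_words = n_words, n_correct = k,
             proportion = k / n_words)
}

#' Configuration of a synthetic envelope-tracking study
#'
#' The defaults emulate the study design the generator stands in for:
#' 64-channel EEG, two attention conditions, matrix-sentence trials of two
#' 20-sentence lists at seven SNRs between -12.5 and +2.5 dB, logistic
#' SNR-to-tracking-gain mappings with condition-specific midpoints
#' (attention -9.15 dB, movie -6.96 dB), 1/f background noise and frontal
#' blink artifacts. `tracking_gain` may be a single function of SNR or a
#' named list of per-condition functions.
#'
#' @param n_subjects number of subjects (default 10).
#' @param snr_grid SNRs in dB (default seven values, -12.5 to +2.5).
#' @param conditions condition names (default attention, movie).
#' @param tracking_gain function(SNR) in `[0, 1]`, or named list per
#'   condition; default per-condition logistics.
#' @param noise list with `rms` and `exponent`, as in [gen_eeg()].
#' @param artifacts list as in [gen_eeg()]; per-condition overrides may be
#'   supplied as `artifacts$tetris` etc.
#' @param fs sampling rate of the generated EEG (default 256).
#' @param n_repetitions presentations per SNR and condition (default 1).
#' @param training_duration_s duration of the per-subject continuous
#'   training stimulus (default 180 s).
#' @param seed integer master seed.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_subjects = 10L,
                         snr_grid = c(-12.5, -10, -7.5, -5, -2.5, 0, 2.5),
                         conditions = c("attention", "movie"),
                         tracking_gain = NULL,
                         noise = list(rms = 20, exponent = 1),
                         artifacts = list(blink_rate = 12, blink_amp = 150,
                                          glitch_rate = 0, glitch_amp = 800),
                         fs = 256, n_repetitions = 1L,
                         training_duration_s = 180,
                         trial_lists = 2L, trial_sentences_per_list = 20L,
                         seed = 1L) {
  if (length(snr_grid) == 0L) stop_invalid("`snr_grid` must not be empty")
  if (n_subjects < 1L) stop_invalid("`n_subjects` must be at least 1")
  if (is.null(tracking_gain)) {
    tracking_gain <- list(
      attention = function(snr) 1 / (1 + exp(-(snr + 9.15) / 2)),
      movie = function(snr) 1 / (1 + exp(-(snr + 6.96) / 2)),
      tetris = function(snr) 0.2 / (1 + exp(-(snr + 6.96) / 2)))
  }
  structure(list(n_subjects = as.integer(n_subjects), snr_grid = snr_grid,
                 conditions = conditions, tracking_gain = tracking_gain,
                 noise = noise, artifacts = artifacts, fs = fs,
                 n_repetitions = as.integer(n_repetitions),
                 training_duration_s = training_duration_s,
                 trial_lists = as.integer(trial_lists),
                 trial_sentences_per_list = as.integer(trial_sentences_per_list),
                 seed = as.integer(seed)),
            class = "study_config")
}

condition_gain <- function(config, condition, snr) {
  tg <- config$tracking_gain
  f <- if (is.function(tg)) tg else tg[[condition]]
  if (is.null(f)) stop_invalid(sprintf("no tracking gain for condition '%s'",
                                       condition))
  g <- f(snr)
  if (any(g < 0 | g > 1)) stop_invalid("tracking gain outside [0, 1]")
  g
}

condition_artifacts <- function(config, condition) {
  base <- config$artifacts
  extra <- base[[condition]]
  base <- base[!vapply(base, is.list, TRUE)]
  if (is.list(extra)) modifyList(base, extra) else base
}

#' Generate one synthetic subject
#'
#' @param config a [study_config()].
#' @param subject integer subject index (1-based).
#' @return list with `training` (continuous attended trial used for decoder
#'   training) and `trials` (one per condition x SNR x repetition), each a
#'   list of `eeg`, `envelope` and `meta`.
#' @export
gen_subject <- function(config, subject) {
  kernels <- list(attention = reference_kernel("attention", fs = config$fs),
                  movie = reference_kernel("movie", fs = config$fs))
  kernels$tetris <- kernels$movie
  sseed <- derive_seed(config$seed, subject)
  # training stimulus: continuous attended speech in quiet
  n_sent <- max(2L, as.integer(ceiling(config$training_duration_s / 3)))
  tl_tr <- gen_matrix_timeline(1L, n_sent, seed = derive_seed(sseed, 1))
  env_tr <- gen_envelope(tl_tr, fs = config$fs, seed = derive_seed(sseed, 2))
  gain_quiet <- condition_gain(config, "attention", 20)
  eeg_tr <- gen_eeg(env_tr, kernels$attention, gain = gain_quiet,
                    noise_cfg = config$noise,
                    artifact_cfg = condition_artifacts(config, "attention"),
                    seed = derive_seed(sseed, 3))
  training <- list(eeg = eeg_tr, envelope = env_tr,
                   meta = list(condition = "story", snr = NA_real_,
                               repetition = 1L))
  trials <- list()
  ti <- 0L
  for (cond in config$conditions) {
    for (snr in config$snr_grid) {
      for (rep_i in seq_len(config$n_repetitions)) {
        ti <- ti + 1L
        tseed <- derive_seed(sseed, 100 + ti)
        tl <- gen_matrix_timeline(config$trial_lists,
                                  config$trial_sentences_per_list,
                                  seed = derive_seed(tseed, 1))
        env <- gen_envelope(tl, fs = config$fs, seed = derive_seed(tseed, 2))
        eeg <- gen_eeg(env, kernels[[cond]],
                       gain = condition_gain(config, cond, snr),
                       noise_cfg = config$noise,
                       artifact_cfg = condition_artifacts(config, cond),
                       seed = derive_seed(tseed, 3))
        trials[[ti]] <- list(eeg = eeg, envelope = env,
                             meta = list(condition = cond, snr = snr,
                                         repetition = rep_i))
      }
    }
  }
  list(subject = subject, training = training, trials = trials)
}

#' Generate a full synthetic study
#'
#' Materialises every subject of the configured study in memory. For large
#' studies prefer passing the config directly to [run_study()], which
#' generates and processes one subject at a time.
#'
#' @param config a [study_config()].
#' @return object of class `synthetic_study`: list of subjects plus the
#'   config.
#' @export
gen_study <- function(config = study_config()) {
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) gen_subject(config, i))
  structure(list(subjects = subjects, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d subjects x %d trials (+1 training each)\n",
              length(x$subjects), length(x$subjects[[1]]$trials)))
  invisible(x)
}
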