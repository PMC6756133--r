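# File interchange: WAV audio, the study directory layout (CSV arrays with
# JSON sidecars) and JSON serialisation of decoders/TRFs.

#' Read a mono/stereo PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 16/32-bit integer PCM and 32/64-bit float,
#' returning samples scaled to `[-1, 1]` for integer formats.
#'
#' @param path file path.
#' @return list with `samples` (samples x channels matrix) and `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop_invalid("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt_raw <- readBin(con, "raw", sz)
      u16 <- function(off) sum(as.integer(fmt_raw[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(fmt_raw[off + 1:4]) * 256^(0:3))
      fmt <- list(format = u16(0), channels = u16(2), fs = u32(4),
                  bits = u16(14))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop_invalid("missing fmt or data chunk")
  if (fmt$format == 1 && fmt$bits == 16) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 1 && fmt$bits == 32) {
    x <- readBin(data_raw, "integer", length(data_raw) / 4, 4,
                 endian = "little") / 2147483648
  } else if (fmt$format == 3 && fmt$bits == 32) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, 4,
                 endian = "little")
  } else if (fmt$format == 3 && fmt$bits == 64) {
    x <- readBin(data_raw, "double", length(data_raw) / 8, 8,
                 endian = "little")
  } else stop_invalid("unsupported WAV encoding")
  list(samples = matrix(x, ncol = fmt$channels, byrow = TRUE), fs = fmt$fs)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in `[-1, 1]` (clipped otherwise).
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @export
write_wav <- function(samples, fs, path) {
  x <- as.integer(pmin(pmax(round(samples * 32768), -32768), 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")              # PCM, mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, 4, endian = "little")    # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")             # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(x, con, 2, endian = "little")
  invisible(path)
}

# ---- study directory layout -------------------------------------------------
# One directory per subject; each trial is an EEG CSV (channels as columns)
# plus a JSON sidecar with rate, labels and metadata; the envelope is a CSV.

write_trial <- function(trial, dir, stem) {
  data.table::fwrite(data.table::as.data.table(t(trial$eeg$data)),
                     file.path(dir, paste0(stem, "_eeg.csv")))
  data.table::fwrite(data.table::data.table(envelope = trial$envelope$samples),
                     file.path(dir, paste0(stem, "_env.csv")))
  meta <- c(trial$meta,
            list(fs_eeg = trial$eeg$fs, fs_env = trial$envelope$fs,
                 labels = trial$eeg$labels))
  jsonlite::write_json(meta, file.path(dir, paste0(stem, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

read_trial <- function(dir, stem) {
  meta <- jsonlite::read_json(file.path(dir, paste0(stem, "_meta.json")),
                              simplifyVector = TRUE)
  eegm <- as.matrix(data.table::fread(file.path(dir, paste0(stem, "_eeg.csv"))))
  env <- data.table::fread(file.path(dir, paste0(stem, "_env.csv")))$envelope
  list(eeg = eeg_recording(t(eegm), meta$fs_eeg, labels = meta$labels),
       envelope = envelope_signal(env, meta$fs_env),
       meta = list(condition = meta$condition,
                   snr = if (is.null(meta$snr)) NA_real_ else meta$snr,
                   repetition = meta$repetition))
}

#' Write a synthetic study to a directory tree
#'
#' Creates one sub-directory per subject containing the training trial and
#' every test trial as CSV arrays with JSON sidecars, plus the study config.
#'
#' @param study a [gen_study()] object.
#' @param root output directory (created if missing).
#' @return `root`, invisibly.
#' @export
write_study <- function(study, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  cfg$tracking_gain <- NULL # closures are not serialisable
  jsonlite::write_json(unclass(cfg), file.path(root, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (sub in study$subjects) {
    sdir <- file.path(root, sprintf("sub-%02d", sub$subject))
    dir.create(sdir, showWarnings = FALSE)
    write_trial(sub$training, sdir, "training")
    for (i in seq_along(sub$trials))
      write_trial(sub$trials[[i]], sdir, sprintf("trial-%03d", i))
  }
  invisible(root)
}

#' Read a study directory
#'
#' @param root directory written by [write_study()] (or following the same
#'   layout).
#' @return a `synthetic_study`-shaped list of subjects.
#' @export
read_study <- function(root) {
  sdirs <- sort(list.dirs(root, recursive = FALSE))
  subjects <- lapply(seq_along(sdirs), function(i) {
    sdir <- sdirs[i]
    stems <- sort(unique(sub("_meta\\.json$", "",
                             list.files(sdir, pattern = "_meta\\.json$"))))
    training <- NULL
    trials <- list()
    for (st in stems) {
      tr <- read_trial(sdir, st)
      if (identical(tr$meta$condition, "story")) training <- tr
      else trials[[length(trials) + 1L]] <- tr
    }
    list(subject = i, training = training, trials = trials)
  })
  structure(list(subjects = subjects, config = NULL),
            class = "synthetic_study")
}

#' Serialise a decoder or TRF to JSON
#'
#' @param model a `backward_decoder` or `forward_trf`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "backward_decoder")) {
    obj <- list(type = "backward_decoder", weights = model$weights,
                labels = model$labels, lambda = model$lambda,
                lag_start_ms = model$lagspec$start_ms,
                lag_end_ms = model$lagspec$end_ms, fs = model$lagspec$fs,
                band = model$band)
  } else if (inherits(model, "forward_trf")) {
    obj <- list(type = "forward_trf", kernel = model$kernel,
                labels = model$labels, lag_ms = model$lag_ms,
                fs = model$lagspec$fs)
  } else stop_invalid("unsupported model type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a decoder or TRF written by [write_model_json()]
#'
#' @param path JSON path.
#' @return the reconstructed model object.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "backward_decoder")) {
    ls <- lag_spec(obj$lag_start_ms, obj$lag_end_ms, obj$fs)
    w <- as.matrix(obj$weights)
    rownames(w) <- obj$labels
    structure(list(weights = w, lambda = obj$lambda, lagspec = ls,
                   band = obj$band, labels = obj$labels),
              class = "backward_decoder")
  } else if (identical(obj$type, "forward_trf")) {
    k <- as.matrix(obj$kernel)
    rownames(k) <- obj$labels
    ls <- lag_spec(min(obj$lag_ms), max(obj$lag_ms) + 1e-9, obj$fs)
    structure(list(kernel = k, lag_ms = obj$lag_ms, lagspec = ls,
                   labels = obj$labels),
              class = "forward_trf")
  } else stop_invalid("unrecognised model JSON")
}
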