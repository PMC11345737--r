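# File interfaces: minimal mono RIFF/WAV reader-writer (PCM16 and IEEE
# float32), a plain-text EEG container (TSV matrix + JSON sidecar carrying
# rate and channel labels), and cohort serialization with a manifest.

#' Write a mono WAV file
#'
#' @param wf a [waveform()].
#' @param path output path.
#' @param format `"float32"` (IEEE float, lossless for unit-scale signals)
#'   or `"pcm16"` (samples clipped to [-1, 1] and quantized).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wf, path, format = c("float32", "pcm16")) {
  stopifnot(inherits(wf, "waveform"))
  format <- match.arg(format)
  n <- length(wf$samples)
  bytes_per <- if (format == "float32") 4L else 2L
  fmt_code <- if (format == "float32") 3L else 1L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(wf$rate), con, size = 4, endian = "little")
  writeBin(as.integer(wf$rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(wf$samples, con, size = 4, endian = "little")
  } else {
    q <- as.integer(round(pmax(pmin(wf$samples, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports PCM16 and IEEE float32 mono files as written by [write_wav()].
#'
#' @param path WAV file path.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop_invalid("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop_invalid("not a WAV file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(code = readBin(con, integer(), size = 2, endian = "little"),
                  channels = readBin(con, integer(), size = 2, endian = "little"),
                  rate = readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, "raw", n = size - 8))
    } else if (id == "data") {
      if (is.null(fmt)) stop_invalid("malformed WAV: data before fmt")
      if (fmt$channels != 1) stop_invalid("only mono WAV supported")
      samples <- if (fmt$code == 3)
        readBin(con, numeric(), n = size / 4, size = 4, endian = "little")
      else if (fmt$code == 1)
        readBin(con, integer(), n = size / 2, size = 2, signed = TRUE,
                endian = "little") / 32767
      else stop_invalid("unsupported WAV format code ", fmt$code)
      if (size %% 2 == 1) invisible(readBin(con, "raw", n = 1))
    } else {
      invisible(readBin(con, "raw", n = size + size %% 2))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop_invalid("no data chunk in ", path)
  waveform(samples, fmt$rate)
}

#' Write an EEG recording as TSV plus JSON sidecar
#'
#' The TSV holds samples x channels with channel labels as header; the
#' sidecar `<path>.json` records the sampling rate and labels.
#'
#' @param rec an [eeg_recording()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$data)
  colnames(m) <- rec$channel_labels
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(rate = rec$rate, labels = rec$channel_labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EEG recording written by [write_eeg()]
#'
#' @param path TSV path (expects `<path>.json` alongside).
#' @return an [eeg_recording()].
#' @export
read_eeg <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  eeg_recording(t(m), meta$rate, meta$labels)
}

#' Write an envelope as single-column delimited text
#'
#' One sample per line under an `envelope` header; the rate is stored in a
#' `# rate: <Hz>` comment on the first line.
#'
#' @param env an [env_signal()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(env, path) {
  stopifnot(inherits(env, "env_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate: %.10g", env$rate), "envelope",
               sprintf("%.17g", env$samples)), con)
  invisible(path)
}

#' Read an envelope written by [write_envelope()]
#'
#' @param path envelope TSV path.
#' @return an [env_signal()].
#' @export
read_envelope <- function(path) {
  first <- readLines(path, n = 1)
  rate <- as.numeric(sub("# rate:", "", first, fixed = TRUE))
  if (!is.finite(rate)) stop_invalid("missing rate header in ", path)
  env_signal(utils::read.table(path, header = TRUE, comment.char = "#")$envelope,
             rate)
}

write_kernel <- function(kernel, path) {
  m <- t(kernel$weights)
  colnames(m) <- kernel$channel_labels
  df <- cbind(lag_ms = kernel$lag_axis_ms, as.data.frame(m, check.names = FALSE))
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_kernel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  trf_kernel(t(as.matrix(df[, -1, drop = FALSE])), df$lag_ms,
             colnames(df)[-1])
}

#' Serialize a synthetic cohort to a directory
#'
#' Per cell: the training and test stimuli as float32 WAVs, training/test
#' EEG as TSV + JSON containers, the ground-truth kernel as TSV, and a JSON
#' metadata file; plus `manifest.tsv` (subject, language, degradation, file
#' paths) and `config.json`. [run_from_files()] consumes the manifest.
#'
#' @param cohort a `synthetic_cohort` built with `keep_audio = TRUE`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in seq_along(cohort$cells)) {
    for (cid in names(cohort$cells[[s]])) {
      cell <- cohort$cells[[s]][[cid]]
      if (is.null(cell$stimulus_train))
        stop_invalid("cohort was built with keep_audio = FALSE; cannot serialize")
      tag <- sprintf("s%02d_%s", s, gsub(":", "_", cid))
      wav_tr <- file.path(dir, paste0(tag, "_train.wav"))
      wav_te <- file.path(dir, paste0(tag, "_test.wav"))
      tr <- file.path(dir, paste0(tag, "_train_eeg.tsv"))
      te <- file.path(dir, paste0(tag, "_test_eeg.tsv"))
      kf <- file.path(dir, paste0(tag, "_kernel.tsv"))
      mf <- file.path(dir, paste0(tag, "_meta.json"))
      write_wav(cell$stimulus_train, wav_tr)
      write_wav(cell$stimulus_test, wav_te)
      write_eeg(cell$train_eeg, tr)
      write_eeg(cell$test_eeg, te)
      write_kernel(cell$kernel, kf)
      jsonlite::write_json(list(subject = s, language = cell$condition$language,
                                degradation = cell$condition$degradation,
                                kernel = basename(kf)),
                           mf, auto_unbox = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, language = cell$condition$language,
        degradation = cell$condition$degradation,
        train_wav = basename(wav_tr), test_wav = basename(wav_te),
        train_eeg = basename(tr),
        test_eeg = basename(te), kernel = basename(kf), meta = basename(mf),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
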