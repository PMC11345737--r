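# Core containers. Lightweight S3: a list with a numeric payload plus the
# sampling rate, mirroring how signal-processing toolboxes carry metadata.

#' Mono audio waveform
#'
#' @param samples numeric vector of audio samples (arbitrary units).
#' @param rate sampling rate in samples/second.
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop_invalid("waveform needs at least one sample")
  if (!all(is.finite(samples))) stop_invalid("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop_invalid("rate must be a positive scalar")
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Broadband amplitude envelope
#'
#' Nonnegative envelope signal, by convention at 100 Hz for decoding.
#'
#' @param samples numeric vector, clipped at 0.
#' @param rate sampling rate in samples/second (default 100).
#' @return an object of class `env_signal`.
#' @export
env_signal <- function(samples, rate = 100) {
  samples <- pmax(as.numeric(samples), 0)
  if (!all(is.finite(samples))) stop_invalid("envelope must be finite")
  if (rate <= 0) stop_invalid("rate must be positive")
  structure(list(samples = samples, rate = rate), class = "env_signal")
}

#' @export
print.env_signal <- function(x, ...) {
  cat(sprintf("<envelope> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Multichannel EEG recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param rate sampling rate in samples/second.
#' @param channel_labels character vector of unique channel names; defaults
#'   to `Ch1..ChN`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_labels = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop_invalid("EEG data must be finite")
  if (rate <= 0) stop_invalid("rate must be positive")
  if (is.null(channel_labels)) channel_labels <- paste0("Ch", seq_len(nrow(data)))
  if (anyDuplicated(channel_labels)) stop_invalid("channel labels must be unique")
  if (length(channel_labels) != nrow(data))
    stop_invalid("one label per channel required")
  structure(list(data = data, rate = rate, channel_labels = channel_labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Ground-truth temporal response function kernel
#'
#' Forward-model kernel relating the stimulus envelope to each EEG channel,
#' used by the simulator; its lags are positive (response follows stimulus).
#'
#' @param weights channels x lags matrix (microvolts per unit envelope).
#' @param lag_axis_ms strictly increasing lag axis in milliseconds.
#' @param channel_labels channel identifiers.
#' @return an object of class `trf_kernel`.
#' @export
trf_kernel <- function(weights, lag_axis_ms, channel_labels = NULL) {
  weights <- as.matrix(weights)
  if (!all(is.finite(weights))) stop_invalid("kernel weights must be finite")
  if (ncol(weights) != length(lag_axis_ms))
    stop_invalid("lag axis must match kernel columns")
  if (any(diff(lag_axis_ms) <= 0)) stop_invalid("lag axis must be increasing")
  if (is.null(channel_labels)) channel_labels <- paste0("Ch", seq_len(nrow(weights)))
  structure(list(weights = weights, lag_axis_ms = as.numeric(lag_axis_ms),
                 channel_labels = channel_labels),
            class = "trf_kernel")
}

# --- experimental conditions ------------------------------------------------

DEGRADATIONS <- c("unprocessed", "vocoded", "vocoded_blur")
LANGUAGES <- c("A", "B")

#' Condition label in the 2 x 3 design
#'
#' Language A is the intelligible-language analogue; the three degradation
#' levels correspond to clean speech, a 16-channel vocoder, and the vocoder
#' with current-spread blurring.
#'
#' @param language "A" or "B".
#' @param degradation one of "unprocessed", "vocoded", "vocoded_blur".
#' @return an object of class `condition_label`.
#' @export
condition_label <- function(language, degradation) {
  language <- match.arg(language, LANGUAGES)
  degradation <- match.arg(degradation, DEGRADATIONS)
  structure(list(language = language, degradation = degradation),
            class = "condition_label")
}

#' All six language x degradation conditions
#'
#' @return list of the 6 `condition_label` objects in fixed order.
#' @export
all_conditions <- function() {
  out <- list()
  for (lang in LANGUAGES) for (deg in DEGRADATIONS)
    out[[length(out) + 1L]] <- condition_label(lang, deg)
  out
}

condition_id <- function(cond) paste(cond$language, cond$degradation, sep = ":")

degradation_level <- function(degradation) {
  match(degradation, DEGRADATIONS) - 1L
}
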