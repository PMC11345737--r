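# Broadband envelope extraction and syllable-landmark timing statistics.

#' Extract the broadband speech amplitude envelope
#'
#' Passes the audio through a gammatone filterbank (default 28 filters
#' equally spaced on the ERB-rate scale between 50 and 5000 Hz), rectifies
#' (absolute value) and compresses each sub-band with a power law, averages
#' the sub-band envelopes, lowpass filters the result at 10 Hz with a
#' zero-phase 8th-order Butterworth, resamples to 100 Hz and clips at zero.
#'
#' The band-averaged envelope is resampled to an intermediate 400 Hz before
#' the 10 Hz lowpass purely for numerical conditioning of the high-order
#' filter; the anti-alias stage at 200 Hz cannot affect a signal that is
#' subsequently lowpassed at 10 Hz.
#'
#' @param audio a [waveform()].
#' @param n_filters number of gammatone bands.
#' @param f_lo,f_hi filterbank limits in Hz; requires `audio$rate >= 2 * f_hi`.
#' @param power_exponent power-law compression exponent applied to the
#'   rectified sub-band signals.
#' @param lowpass_hz final lowpass corner in Hz.
#' @param out_rate output envelope rate in Hz.
#' @return an [env_signal()] at `out_rate`.
#' @export
extract_envelope <- function(audio, n_filters = 28, f_lo = 50, f_hi = 5000,
                             power_exponent = 0.6, lowpass_hz = 10,
                             out_rate = 100) {
  stopifnot(inherits(audio, "waveform"))
  if (audio$rate < 2 * f_hi)
    stop_invalid("audio rate must be at least twice the top filterbank frequency")
  cfs <- erb_space(f_lo, f_hi, n_filters)
  acc <- numeric(length(audio$samples))
  for (cf in cfs)
    acc <- acc + abs(gammatone_filter(audio$samples, cf, audio$rate))^power_exponent
  env <- acc / n_filters
  work_rate <- 400
  if (audio$rate > work_rate) env <- resample_signal(env, audio$rate, work_rate)
  else work_rate <- audio$rate
  env <- butter_filtfilt(env, 8, lowpass_hz, work_rate, "low")
  env <- resample_signal(env, work_rate, out_rate)
  env_signal(env, out_rate)
}

#' Center frequencies of the envelope filterbank
#'
#' @inheritParams extract_envelope
#' @return increasing vector of gammatone center frequencies in Hz.
#' @export
envelope_filterbank_cfs <- function(n_filters = 28, f_lo = 50, f_hi = 5000) {
  erb_space(f_lo, f_hi, n_filters)
}

#' Detect vowel onset-like acoustic landmarks
#'
#' Simplified landmark detector: peaks in the rate-of-rise of a smoothed
#' (10 Hz lowpass) rectified envelope, thresholded within consecutive 2 s
#' windows at a fraction of each window's maximum rise. Intended to emulate
#' syllable-onset timing statistics, not any specific published detector.
#'
#' @param audio a [waveform()] of at least `window_s` duration.
#' @param window_s analysis window in seconds.
#' @param thresh_frac per-window threshold as a fraction of the window's
#'   maximum rate-of-rise.
#' @param min_separation_s minimum spacing between landmarks in seconds.
#' @return object of class `landmark_series`: list with `onset_times`
#'   (increasing, seconds) and `window_s`.
#' @export
detect_landmarks <- function(audio, window_s = 2, thresh_frac = 0.3,
                             min_separation_s = 0.08) {
  stopifnot(inherits(audio, "waveform"))
  dur <- length(audio$samples) / audio$rate
  if (dur < window_s) stop_invalid("audio must be at least one window long")
  er <- 100
  env <- abs(audio$samples)
  env <- resample_signal(env, audio$rate, er)
  env <- pmax(butter_filtfilt(env, 4, 10, er, "low"), 0)
  rise <- pmax(c(0, diff(env)) * er, 0)
  # global silence guard: no energy, no landmarks
  if (max(env) <= 0 || max(rise) <= .Machine$double.eps * 100)
    return(structure(list(onset_times = numeric(0), window_s = window_s),
                     class = "landmark_series"))
  n <- length(rise)
  peaks <- which(rise[2:(n - 1)] > rise[1:(n - 2)] &
                   rise[2:(n - 1)] >= rise[3:n]) + 1L
  win <- floor((peaks - 1) / (window_s * er))
  keep <- logical(length(peaks))
  floor_rise <- 1e-4 * max(rise)
  for (w in unique(win)) {
    idx <- which(win == w)
    thr <- max(thresh_frac * max(rise[peaks[idx]]), floor_rise)
    keep[idx] <- rise[peaks[idx]] >= thr
  }
  peaks <- peaks[keep]
  # enforce minimum separation, keeping the larger peak
  if (length(peaks) > 1) {
    sel <- peaks[1]
    for (p in peaks[-1]) {
      if ((p - sel[length(sel)]) / er >= min_separation_s) sel <- c(sel, p)
      else if (rise[p] > rise[sel[length(sel)]]) sel[length(sel)] <- p
    }
    peaks <- sel
  }
  structure(list(onset_times = (peaks - 1) / er, window_s = window_s),
            class = "landmark_series")
}

#' Inter-onset-interval statistics in fixed windows
#'
#' Computes per-window (default 2 s) inter-onset-interval means and
#' coefficients of variation from a landmark series, then grand averages
#' across windows. The CV uses the population standard deviation.
#'
#' @param landmarks a `landmark_series` from [detect_landmarks()].
#' @return list with `per_window` (data.frame: window, n_onsets, mean_ioi_ms,
#'   cv_ioi) and `grand` (mean_ioi_ms, sd_ioi_ms, mean_cv, sd_cv); both empty
#'   with a warning when fewer than 2 landmarks are available.
#' @export
ioi_stats <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_series"))
  empty <- list(per_window = data.frame(window = integer(0), n_onsets = integer(0),
                                        mean_ioi_ms = numeric(0), cv_ioi = numeric(0)),
                grand = list(mean_ioi_ms = NA_real_, sd_ioi_ms = NA_real_,
                             mean_cv = NA_real_, sd_cv = NA_real_))
  if (length(landmarks$onset_times) < 2) {
    warning("fewer than 2 landmarks; empty IOI statistics")
    return(empty)
  }
  w <- floor(landmarks$onset_times / landmarks$window_s)
  rows <- lapply(unique(w), function(wi) {
    t <- landmarks$onset_times[w == wi]
    if (length(t) < 2) return(NULL)
    ioi <- diff(t) * 1000
    m <- mean(ioi)
    s <- sqrt(mean((ioi - m)^2))     # population SD
    data.frame(window = wi, n_onsets = length(t), mean_ioi_ms = m,
               cv_ioi = if (m > 0) s / m else NA_real_)
  })
  per_window <- do.call(rbind, rows)
  if (is.null(per_window) || nrow(per_window) == 0) {
    warning("no window contains 2+ landmarks; empty IOI statistics")
    return(empty)
  }
  list(per_window = per_window,
       grand = list(mean_ioi_ms = mean(per_window$mean_ioi_ms),
                    sd_ioi_ms = sd(per_window$mean_ioi_ms),
                    mean_cv = mean(per_window$cv_ioi, na.rm = TRUE),
                    sd_cv = sd(per_window$cv_ioi, na.rm = TRUE)))
}

#' Pearson correlation between two envelopes
#'
#' @param e1,e2 [env_signal()] objects at the same rate. Lengths are
#'   truncated to the shorter with a warning if they differ.
#' @return Pearson r; 0 with a warning if either envelope is constant.
#' @export
envelope_correlation <- function(e1, e2) {
  stopifnot(inherits(e1, "env_signal"), inherits(e2, "env_signal"))
  if (e1$rate != e2$rate) stop_invalid("envelope rates differ")
  n1 <- length(e1$samples); n2 <- length(e2$samples)
  if (n1 != n2) {
    warning("envelope lengths differ; truncating to the shorter")
    n <- min(n1, n2)
  } else n <- n1
  pearson_r(e1$samples[seq_len(n)], e2$samples[seq_len(n)])
}
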