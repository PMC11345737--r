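# Channel vocoder with optional current-spread "blurring":
# cochlear-implant-like spectral degradation reduced to the two parameters
# that define it — the analysis channel count and the spread decay slope in
# dB per octave of channel separation.

#' Design a contiguous ERB-spaced analysis filterbank
#'
#' `n_channels` contiguous bands with corner frequencies equally spaced on
#' the ERB-rate scale over `[f_lo, f_hi]`. Each band is realized as a
#' zero-phase highpass/lowpass Butterworth cascade; interior corners are
#' shared between neighbors, so after forward-backward filtering adjacent
#' bands cross at -6 dB and their summed magnitudes stay flat. The outermost
#' corners are relaxed outward so the first and last bands reach full gain
#' at `f_lo` and `f_hi`.
#'
#' @param n_channels number of analysis bands.
#' @param f_lo,f_hi filterbank limits in Hz; `f_lo < f_hi < rate/2`. The
#'   default upper limit is 8000 Hz, capped just below the Nyquist frequency
#'   for lower-rate audio.
#' @param rate audio sampling rate in Hz.
#' @param order one-pass Butterworth order per skirt (even).
#' @return object of class `vocoder_filterbank`: list with `edges` (length
#'   `n_channels + 1`), `center_freqs`, `rate`, `order`, and per-band filter
#'   sections.
#' @export
design_filterbank <- function(n_channels = 16, f_lo = 100, f_hi = NULL, rate,
                              order = 4) {
  if (n_channels < 1) stop_invalid("need at least one channel")
  f_hi <- f_hi %||% min(8000, 0.44 * rate)
  if (!(f_lo < f_hi && f_hi < rate / 2))
    stop_invalid("need f_lo < f_hi < rate/2")
  edges <- erb_space(f_lo, f_hi, n_channels + 1)
  centers <- erb_rate_inv((erb_rate(edges[-1]) + erb_rate(edges[-length(edges)])) / 2)
  # outer corners relaxed so |H|^2 ~ 1 at the nominal outer edges
  relax <- 0.7
  bands <- lapply(seq_len(n_channels), function(i) {
    lo <- if (i == 1) edges[1] * relax else edges[i]
    hi <- if (i == n_channels) min(edges[n_channels + 1] / relax, rate / 2 * 0.99)
          else edges[i + 1]
    list(hp = butter_sections(order, lo, rate, "high"),
         lp = butter_sections(order, hi, rate, "low"))
  })
  structure(list(edges = edges, center_freqs = centers, rate = rate,
                 order = order, bands = bands),
            class = "vocoder_filterbank")
}

band_filtfilt <- function(fb, i, x) {
  y <- filtfilt_sections(fb$bands[[i]]$hp, x,
                         pad = min(length(x) - 1L, ceiling(3 * fb$rate / fb$edges[1])))
  filtfilt_sections(fb$bands[[i]]$lp, y,
                    pad = min(length(x) - 1L, ceiling(3 * fb$rate / fb$edges[1])))
}

#' Effective magnitude response of a filterbank on a frequency grid
#'
#' @param fb a `vocoder_filterbank`.
#' @param freqs frequencies in Hz.
#' @return bands x frequencies matrix of effective (zero-phase) magnitudes.
#' @export
filterbank_response <- function(fb, freqs) {
  t(vapply(fb$bands, function(bd)
    sections_response(bd$hp, freqs, fb$rate) *
      sections_response(bd$lp, freqs, fb$rate),
    numeric(length(freqs))))
}

#' Current-spread mixing matrix
#'
#' Cross-channel envelope mixing gains decaying with octave distance between
#' channel center frequencies: `gains[i, j] = 10^(slope |log2(f_j / f_i)| / 20)`,
#' with each row renormalized to unit sum so blurring conserves total
#' envelope energy.
#'
#' @param center_freqs strictly increasing positive channel frequencies (Hz).
#' @param slope_db_per_octave decay slope, dB per octave (negative).
#' @return object of class `spread_matrix`: list with row-normalized `gains`
#'   (and the un-normalized `raw_gains`) plus `center_freqs`.
#' @export
spread_matrix <- function(center_freqs, slope_db_per_octave = -16) {
  if (any(center_freqs <= 0)) stop_invalid("center frequencies must be positive")
  if (any(diff(center_freqs) <= 0))
    stop_invalid("center frequencies must be strictly increasing")
  d <- abs(outer(log2(center_freqs), log2(center_freqs), "-"))
  raw <- 10^(slope_db_per_octave * d / 20)
  gains <- raw / rowSums(raw)
  structure(list(gains = gains, raw_gains = raw, center_freqs = center_freqs),
            class = "spread_matrix")
}

#' Per-band envelopes of a vocoder analysis
#'
#' Rectified (absolute value), lowpassed (default 300 Hz, zero-phase 4th
#' order) envelopes of each analysis band, optionally mixed by the
#' current-spread matrix.
#'
#' @param audio a [waveform()].
#' @param n_channels number of analysis bands.
#' @param slope_db_per_octave spread slope in dB/octave, or `NULL` for no
#'   blurring.
#' @param f_lo,f_hi filterbank limits in Hz.
#' @param env_lowpass_hz per-band envelope lowpass corner.
#' @return samples x channels matrix of nonnegative band envelopes, with the
#'   filterbank attached as attribute `"filterbank"`.
#' @export
band_envelopes <- function(audio, n_channels = 16, slope_db_per_octave = NULL,
                           f_lo = 100, f_hi = NULL, env_lowpass_hz = 300) {
  stopifnot(inherits(audio, "waveform"))
  fb <- design_filterbank(n_channels, f_lo, f_hi, audio$rate)
  lp <- min(env_lowpass_hz, audio$rate / 2 * 0.8)
  E <- vapply(seq_len(n_channels), function(i) {
    pmax(butter_filtfilt(abs(band_filtfilt(fb, i, audio$samples)),
                         4, lp, audio$rate, "low"), 0)
  }, numeric(length(audio$samples)))
  if (!is.null(slope_db_per_octave)) {
    S <- spread_matrix(fb$center_freqs, slope_db_per_octave)
    E <- E %*% t(S$gains)
    E[E < 0] <- 0
  }
  attr(E, "filterbank") <- fb
  E
}

#' Vocode audio with optional current-spread blurring
#'
#' Channel vocoder: band envelopes are extracted with [band_envelopes()]
#' (optionally blurred by the spread matrix), each envelope modulates its
#' band's carrier (band-limited noise by default, or a tone at the band
#' center), the bands are summed, and the output RMS is matched to the
#' input. `slope_db_per_octave = NULL` gives the plain "vocoded" condition;
#' -16 gives "vocoded + blurring".
#'
#' @inheritParams band_envelopes
#' @param carrier `"noise"` or `"tone"`.
#' @param seed integer seed for the noise carriers.
#' @return a [waveform()] at the input rate.
#' @export
vocode <- function(audio, n_channels = 16, slope_db_per_octave = NULL,
                   carrier = c("noise", "tone"), seed = 1,
                   f_lo = 100, f_hi = NULL, env_lowpass_hz = 300) {
  carrier <- match.arg(carrier)
  E <- band_envelopes(audio, n_channels, slope_db_per_octave,
                      f_lo, f_hi, env_lowpass_hz)
  fb <- attr(E, "filterbank")
  n <- length(audio$samples)
  out <- numeric(n)
  for (i in seq_len(n_channels)) {
    ci <- if (carrier == "noise") {
      c0 <- with_seed(derive_seed(seed, "carrier", i), rnorm(n))
      band_filtfilt(fb, i, c0)
    } else {
      sin(2 * pi * fb$center_freqs[i] * seq_len(n) / audio$rate)
    }
    crms <- sqrt(mean(ci^2))
    if (crms > 0) ci <- ci / crms
    out <- out + E[, i] * ci
  }
  in_rms <- sqrt(mean(audio$samples^2))
  out_rms <- sqrt(mean(out^2))
  if (out_rms > 0 && in_rms > 0) out <- out * in_rms / out_rms
  waveform(out, audio$rate)
}
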