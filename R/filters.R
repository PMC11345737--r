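# DSP primitives shared by the envelope, vocoder and decoder modules.
# Butterworth filters are assembled from analog-prototype poles as cascaded
# second-order sections and applied forward-backward (zero phase): the
# transfer-function forms returned by generic designers are numerically
# fragile at the very low normalized cutoffs this pipeline needs (e.g. a
# 10 Hz corner at a 16 kHz audio rate).

#' ERB-rate scale conversions
#'
#' Equivalent-rectangular-bandwidth rate scale (Glasberg & Moore):
#' `erb_rate(f) = 21.4 log10(0.00437 f + 1)`.
#'
#' @param f frequency in Hz.
#' @return ERB-rate value(s).
#' @export
erb_rate <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname erb_rate
#' @param e ERB-rate value(s).
#' @export
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Frequencies equally spaced on the ERB-rate scale
#'
#' @param f_lo,f_hi band limits in Hz (inclusive endpoints).
#' @param n number of points.
#' @return numeric vector of length `n`, strictly increasing.
#' @export
erb_space <- function(f_lo, f_hi, n) {
  if (f_lo <= 0 || f_hi <= f_lo) stop_invalid("need 0 < f_lo < f_hi")
  erb_rate_inv(seq(erb_rate(f_lo), erb_rate(f_hi), length.out = n))
}

erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

# Butterworth second-order sections (even order only) via bilinear transform
# of the analog prototype poles.
butter_sections <- function(order, cutoff_hz, rate, type = c("low", "high")) {
  type <- match.arg(type)
  if (order %% 2 != 0 || order < 2) stop_invalid("even filter order required")
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop_invalid("cutoff must lie in (0, rate/2)")
  warp <- 2 * rate * tan(pi * cutoff_hz / rate)
  k <- seq_len(order / 2)
  theta <- pi / 2 + pi * (2 * k - 1) / (2 * order)
  proto <- exp(1i * theta)                       # upper-half-plane prototype poles
  pa <- if (type == "low") warp * proto else warp / proto
  pz <- (1 + pa / (2 * rate)) / (1 - pa / (2 * rate))
  lapply(seq_along(pz), function(i) {
    a <- c(1, -2 * Re(pz[i]), Mod(pz[i])^2)
    b0 <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
    gain <- if (type == "low") sum(a) / 4 else (a[1] - a[2] + a[3]) / 4
    list(b = b0 * gain, a = a)
  })
}

apply_sections <- function(sections, x) {
  for (s in sections) x <- iir_filter_cpp(s$b, s$a, x)
  x
}

# Forward-backward filtering with odd-reflection padding (scipy-style edges).
filtfilt_sections <- function(sections, x, pad = NULL) {
  n <- length(x)
  pad <- min(n - 1L, pad %||% (3L * 10L * length(sections)))
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(pre, x, post)
  } else xp <- x
  y <- apply_sections(sections, xp)
  y <- rev(apply_sections(sections, rev(y)))
  if (pad > 0) y[seq(pad + 1, pad + n)] else y
}

#' Zero-phase Butterworth filtering
#'
#' Designs an even-order Butterworth low- or highpass as second-order
#' sections and applies it forward and backward. The magnitude response is
#' squared, so the -3 dB design corner becomes a -6 dB point of the
#' effective filter; quoted orders refer to the one-pass design, matching
#' the usual reporting convention for zero-phase pipelines.
#'
#' @param x numeric signal.
#' @param order one-pass filter order (even).
#' @param cutoff_hz corner frequency in Hz.
#' @param rate sampling rate in Hz.
#' @param type "low" or "high".
#' @return filtered signal, same length as `x`.
#' @export
butter_filtfilt <- function(x, order, cutoff_hz, rate, type = c("low", "high")) {
  sections <- butter_sections(order, cutoff_hz, rate, type)
  pad <- min(length(x) - 1L, max(200L, ceiling(3 * rate / cutoff_hz)))
  filtfilt_sections(sections, x, pad = pad)
}

# Effective (zero-phase) power response of a section cascade on a frequency grid.
sections_response <- function(sections, freqs, rate) {
  z <- exp(-2i * pi * freqs / rate)
  H <- rep(1 + 0i, length(z))
  for (s in sections) {
    H <- H * (s$b[1] + s$b[2] * z + s$b[3] * z^2) /
      (s$a[1] + s$a[2] * z + s$a[3] * z^2)
  }
  Mod(H)^2
}

#' Fourth-order gammatone filter
#'
#' All-pole IIR gammatone (cascade of four second-order stages sharing the
#' pole pair of the analog gammatone), gain-normalized numerically to unit
#' magnitude at the center frequency. The standard auditory-filterbank
#' building block.
#'
#' @param x numeric signal.
#' @param cf center frequency in Hz.
#' @param rate sampling rate in Hz.
#' @return filtered signal.
#' @export
gammatone_filter <- function(x, cf, rate) {
  Ts <- 1 / rate
  B <- 1.019 * 2 * pi * erb_bandwidth(cf)
  theta <- 2 * pi * cf * Ts
  cosT <- cos(theta); sinT <- sin(theta); eBT <- exp(B * Ts)
  a <- c(1, -2 * cosT / eBT, exp(-2 * B * Ts))
  k1 <- sqrt(3 + 2^1.5); k2 <- sqrt(3 - 2^1.5)
  A1 <- c(-(2 * Ts * cosT / eBT + k1 * Ts * sinT / eBT) / 2,
          -(2 * Ts * cosT / eBT - k1 * Ts * sinT / eBT) / 2,
          -(2 * Ts * cosT / eBT + k2 * Ts * sinT / eBT) / 2,
          -(2 * Ts * cosT / eBT - k2 * Ts * sinT / eBT) / 2)
  z <- exp(-1i * theta)
  H <- prod(vapply(A1, function(a1)
    abs((Ts + a1 * z) / (a[1] + a[2] * z + a[3] * z^2)), 1.0))
  y <- iir_filter_cpp(c(Ts / H, A1[1] / H, 0), a, x)
  for (i in 2:4) y <- iir_filter_cpp(c(Ts, A1[i], 0), a, y)
  y
}

#' Rational polyphase resampling
#'
#' Resamples `x` from `from` Hz to `to` Hz by zero-stuffed upsampling,
#' linear-phase windowed-sinc anti-alias filtering (Hamming, 10 taps per
#' polyphase branch, delay-compensated) and downsampling — the standard
#' upfirdn construction, with exactly unit passband gain.
#'
#' @param x numeric signal.
#' @param from,to sampling rates in Hz (positive; reduced internally).
#' @return resampled signal of length `ceiling(length(x) * to / from)`.
#' @export
resample_signal <- function(x, from, to) {
  if (from <= 0 || to <= 0) stop_invalid("rates must be positive")
  x <- as.numeric(x)
  if (from == to) return(x)
  # reduce to integer ratio (rates are integral in practice; rescale if not)
  scale <- 1
  while (abs(from * scale - round(from * scale)) > 1e-9 ||
         abs(to * scale - round(to * scale)) > 1e-9) scale <- scale * 10
  p <- round(to * scale); q <- round(from * scale)
  g <- gcd_int(p, q)
  L <- p / g; M <- q / g
  n <- length(x)
  if (L > 1) {
    up <- numeric(n * L)
    up[seq(1, n * L, by = L)] <- x
  } else up <- x
  N <- 2 * 10 * max(L, M) + 1
  h <- as.numeric(signal::fir1(N - 1, min(1 / L, 1 / M)))
  h <- L * h / sum(h)                       # exact unit DC gain

  y <- stats::convolve(up, rev(h), type = "open")
  idx <- seq(1 + (N - 1) / 2, by = M, length.out = ceiling(n * L / M))
  y[idx]
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Band power in [f1, f2] Hz via the periodogram (sum of |FFT|^2 bins).
band_power <- function(x, rate, f1, f2) {
  n <- length(x)
  sp <- Mod(fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * rate / n
  sel <- freqs >= f1 & freqs <= f2
  sum(sp[sel])
}
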