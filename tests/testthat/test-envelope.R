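# Envelope extraction, landmark detection and IOI statistics.

test_that("silent audio yields an all-zero envelope", {
  e <- extract_envelope(waveform(numeric(16000 * 2) + 0, 16000))
  expect_true(all(e$samples == 0))
  expect_equal(e$rate, 100)
})

test_that("envelope is homogeneous of degree p in the input amplitude", {
  x <- make_stimulus(5, 5, 16000, seed = 2)
  e1 <- extract_envelope(x)
  e2 <- extract_envelope(waveform(3 * x$samples, x$rate))
  expect_lt(max(abs(e2$samples - 3^0.6 * e1$samples)) / max(e1$samples), 1e-6)
})

test_that("audio rate below twice the top band is rejected", {
  expect_error(extract_envelope(waveform(rnorm(8000), 8000)), "twice")
})

test_that("steady tone envelope is flat and matches the closed-form steady state", {
  rate <- 16000; f0 <- 1000; A <- 0.3; p <- 0.6
  tone <- waveform(A * sin(2 * pi * f0 * (1:(10 * rate)) / rate), rate)
  e <- extract_envelope(tone)
  v <- e$samples[51:(length(e$samples) - 50)]   # discard 0.5 s at each end
  expect_lt(sd(v) / mean(v), 0.02)
  # independent closed-form route: per-band digital gammatone gain at f0
  # (coefficients re-derived here), times E|sin|^p from the Beta integral
  Esin <- gamma((p + 1) / 2) / (sqrt(pi) * gamma(p / 2 + 1))
  gains <- vapply(erb_space(50, 5000, 28), function(cf) {
    Ts <- 1 / rate
    B <- 1.019 * 2 * pi * (24.7 * (4.37 * cf / 1000 + 1))
    th <- 2 * pi * cf * Ts; eBT <- exp(B * Ts)
    a <- c(1, -2 * cos(th) / eBT, exp(-2 * B * Ts))
    k1 <- sqrt(3 + 2^1.5); k2 <- sqrt(3 - 2^1.5)
    A1 <- c(-(2 * Ts * cos(th) / eBT + k1 * Ts * sin(th) / eBT) / 2,
            -(2 * Ts * cos(th) / eBT - k1 * Ts * sin(th) / eBT) / 2,
            -(2 * Ts * cos(th) / eBT + k2 * Ts * sin(th) / eBT) / 2,
            -(2 * Ts * cos(th) / eBT - k2 * Ts * sin(th) / eBT) / 2)
    Hmag <- function(z) prod(vapply(A1, function(a1)
      abs((Ts + a1 * z) / (a[1] + a[2] * z + a[3] * z^2)), 1.0))
    Hmag(exp(-2i * pi * f0 / rate)) / Hmag(exp(-1i * th))
  }, 1.0)
  oracle <- mean((gains * A)^p) * Esin
  expect_equal(mean(v), oracle, tolerance = 0.01)
})

test_that("landmarks recover the modulation rate of 5 Hz AM noise", {
  rate <- 8000; n <- 10 * rate
  set.seed(4)
  am <- waveform(rnorm(n) * (1 + sin(2 * pi * 5 * (1:n) / rate)), rate)
  lm <- detect_landmarks(am)
  rate_hz <- length(lm$onset_times) / 10
  expect_gt(rate_hz, 4); expect_lt(rate_hz, 6)     # within 20% of 5/s
})

test_that("two isolated smooth bursts give two landmarks 1 s apart", {
  rate <- 8000
  x <- numeric(4 * rate)
  bump <- sin(pi * (0:(0.2 * rate)) / (0.2 * rate))^2
  set.seed(5)
  for (t0 in c(1, 2)) {
    i <- round(t0 * rate) + seq_along(bump)
    x[i] <- x[i] + bump * rnorm(length(bump))
  }
  lm <- detect_landmarks(waveform(x, rate))
  expect_length(lm$onset_times, 2)
  expect_equal(diff(lm$onset_times), 1, tolerance = 0.05)
})

test_that("silence yields no landmarks and too-short input errors", {
  expect_length(detect_landmarks(waveform(numeric(3 * 8000) + 0, 8000))$onset_times, 0)
  expect_error(detect_landmarks(waveform(rnorm(8000), 8000)), "window")
})

test_that("IOI statistics match hand computation and degenerate cases", {
  mk <- function(t) structure(list(onset_times = t, window_s = 2),
                              class = "landmark_series")
  s <- ioi_stats(mk(c(0, 0.1, 0.3)))
  expect_equal(s$per_window$mean_ioi_ms, 150)
  expect_equal(s$per_window$cv_ioi, 50 / 150, tolerance = 1e-12)
  # perfectly periodic onsets: zero dispersion
  s2 <- ioi_stats(mk(seq(0, 1.8, by = 0.2)))
  expect_equal(s2$grand$mean_ioi_ms, 200, tolerance = 1e-9)
  expect_equal(s2$grand$mean_cv, 0, tolerance = 1e-9)
  expect_warning(s3 <- ioi_stats(mk(0.5)), "fewer than 2")
  expect_equal(nrow(s3$per_window), 0)
})

test_that("envelope correlation handles identity, affine maps and edge cases", {
  e <- quick_envelope(20, seed = 6)
  expect_equal(envelope_correlation(e, e), 1)
  aff <- env_signal(2 * e$samples + 0.5, e$rate)
  expect_equal(envelope_correlation(e, aff), 1, tolerance = 1e-12)
  expect_error(envelope_correlation(e, env_signal(e$samples, 50)), "rates")
  expect_warning(r <- envelope_correlation(e, env_signal(e$samples[1:100], e$rate)),
                 "truncating")
  flat <- env_signal(rep(1, length(e$samples)), e$rate)
  expect_warning(r0 <- envelope_correlation(e, flat), "constant")
  expect_equal(r0, 0)
  # a reversed envelope decorrelates on average
  rs <- vapply(1:5, function(i) {
    ei <- quick_envelope(60, seed = 100 + i)
    abs(envelope_correlation(ei, env_signal(rev(ei$samples), ei$rate)))
  }, 1.0)
  expect_lt(mean(rs), 0.3)
})
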