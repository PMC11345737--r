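# Simulator: stimuli, condition kernels, forward-model EEG, cohorts.

test_that("stimulus has the requested length, is finite and deterministic", {
  st <- make_stimulus(60, 5, 16000, seed = 1)
  expect_length(st$samples, 960000)
  expect_true(all(is.finite(st$samples)))
  expect_gt(sd(st$samples), 0)
  st2 <- make_stimulus(60, 5, 16000, seed = 1)
  expect_identical(st$samples, st2$samples)
  expect_error(make_stimulus(-1, 5, 16000), "positive")
})

test_that("pulse-train inter-onset intervals match the requested rate and CV", {
  on <- attr(make_stimulus(60, 5, 8000, seed = 2), "onsets")
  ioi <- diff(on)
  expect_equal(mean(ioi) * 1000, 200, tolerance = 0.1 * 200)
  expect_equal(sd(ioi) / mean(ioi), 0.55, tolerance = 0.2)
})

test_that("no-effect configuration gives identical kernels across conditions", {
  cfg <- quick_config(language_gain = 1, degradation_shape_jitter = 0)
  ks <- lapply(all_conditions(), function(cc) make_condition_kernel(5, cc, cfg, 6))
  for (k in ks[-1]) expect_identical(k$weights, ks[[1]]$weights)
})

test_that("language gain scales the kernel norm exactly", {
  cfg <- quick_config(language_gain = 1.2, degradation_shape_jitter = 0.3)
  for (deg in c("unprocessed", "vocoded", "vocoded_blur")) {
    ka <- make_condition_kernel(5, condition_label("A", deg), cfg, 6)
    kb <- make_condition_kernel(5, condition_label("B", deg), cfg, 6)
    expect_equal(norm(ka$weights, "F") / norm(kb$weights, "F"), 1.2,
                 tolerance = 1e-12)
  }
})

test_that("stronger degradation perturbs the kernel further from baseline", {
  cfg <- quick_config(degradation_shape_jitter = 0.4)
  cors <- vapply(1:100, function(i) {
    ku <- make_condition_kernel(i, condition_label("B", "unprocessed"), cfg, 6)
    kv <- make_condition_kernel(i, condition_label("B", "vocoded"), cfg, 6)
    kb <- make_condition_kernel(i, condition_label("B", "vocoded_blur"), cfg, 6)
    c(cor(as.vector(ku$weights), as.vector(kv$weights)),
      cor(as.vector(ku$weights), as.vector(kb$weights)))
  }, c(v = 1.0, b = 1.0))
  expect_lt(mean(cors["b", ]), mean(cors["v", ]))
  expect_error(make_condition_kernel(1, condition_label("A", "vocoded"),
                                     quick_config(), 0), "channel")
})

test_that("an impulse kernel without noise copies the envelope onto one channel", {
  env <- quick_envelope(20, seed = 7)
  k <- impulse_kernel(n_channels = 3)
  ee <- synthesize_eeg(env, k, Inf, seed = 1)
  expect_equal(ee$data[1, ], env$samples, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(ee$data[2:3, ] == 0))
  expect_error(synthesize_eeg(env, k, 0, rate = 50), "rate")
})

test_that("requested band-limited SNR is realized within 1 dB", {
  env <- quick_envelope(60, seed = 8)
  cfg <- quick_config()
  k <- make_condition_kernel(11, condition_label("A", "unprocessed"), cfg, 6)
  for (snr in c(-5, 0, 10)) {
    clean <- synthesize_eeg(env, k, Inf, seed = 3)
    noisy <- synthesize_eeg(env, k, snr, seed = 3)
    noise <- noisy$data - clean$data
    ps <- sum(apply(clean$data, 1, function(ch) envtrack:::band_power(ch, 100, 2, 8)))
    pn <- sum(apply(noise, 1, function(ch) envtrack:::band_power(ch, 100, 2, 8)))
    expect_equal(10 * log10(ps / pn), snr, tolerance = 1)
  }
  # determinism
  a <- synthesize_eeg(env, k, 0, seed = 5)
  b <- synthesize_eeg(env, k, 0, seed = 5)
  expect_identical(a$data, b$data)
})

test_that("background noise follows the requested 1/f slope", {
  x <- envtrack:::with_seed(9, envtrack:::one_over_f_noise(60 * 100, 100, 1))
  p_lo <- envtrack:::band_power(x, 100, 1, 2)
  p_hi <- envtrack:::band_power(x, 100, 16, 32)
  # equal per-octave power for 1/f: both octave bands should roughly match
  expect_equal(log2(p_lo / p_hi), 0, tolerance = 1.5)
  expect_equal(sd(x), 1, tolerance = 1e-9)
})

test_that("cohorts have full cardinality, correct durations and reproduce per seed", {
  cfg <- quick_config(n_subjects = 2, trial_duration_s = 20, test_duration_s = 10)
  co <- make_cohort(cfg, keep_audio = FALSE)
  expect_length(co$cells, 2)
  expect_length(co$cells[[1]], 6)
  cell <- co$cells[[2]][["B:vocoded"]]
  expect_equal(length(cell$train_env$samples), 2000)
  expect_equal(length(cell$test_env$samples), 1000)
  expect_equal(ncol(cell$train_eeg$data), 2000)
  expect_equal(nrow(cell$train_eeg$data), 6)
  co2 <- make_cohort(cfg, keep_audio = FALSE)
  expect_identical(cell$train_eeg$data,
                   co2$cells[[2]][["B:vocoded"]]$train_eeg$data)
  expect_identical(cell$train_env$samples,
                   co2$cells[[2]][["B:vocoded"]]$train_env$samples)
})
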