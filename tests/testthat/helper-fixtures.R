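# Shared fixtures: every heavy object is built once per test run at reduced
# scale (low audio rate, short segments, few channels) so the whole suite
# stays fast while exercising the full pipeline.

# reduced settings used by simulation-heavy tests
quick_env_params <- list(n_filters = 12, f_lo = 50, f_hi = 1800)
quick_grid <- 10^seq(-3, 5, by = 2)

quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 2, trial_duration_s = 60, test_duration_s = 30,
         n_channels = 6, audio_rate = 4000, snr_db = 0,
         env_params = quick_env_params, seed = 101),
    list(...))
  do.call(sim_config, args)
}

quick_envelope <- function(duration_s = 60, seed = 1, rate = 4000) {
  extract_envelope(make_stimulus(duration_s, 5, rate, seed = seed),
                   n_filters = 12, f_lo = 50, f_hi = 1800)
}

# one cell split into train/test segments at the 100 Hz decoding rate
split_cell <- function(env, eeg, train_s) {
  n_tr <- round(train_s * env$rate)
  n <- min(length(env$samples), ncol(eeg$data))
  list(train_env = env_signal(env$samples[1:n_tr], env$rate),
       test_env = env_signal(env$samples[(n_tr + 1):n], env$rate),
       train_eeg = eeg_recording(eeg$data[, 1:n_tr, drop = FALSE], eeg$rate,
                                 eeg$channel_labels),
       test_eeg = eeg_recording(eeg$data[, (n_tr + 1):n, drop = FALSE],
                                eeg$rate, eeg$channel_labels))
}

impulse_kernel <- function(n_channels = 4, hot_channel = 1, hot_lag = 1) {
  w <- matrix(0, n_channels, 36)
  w[hot_channel, hot_lag] <- 1
  trf_kernel(w, seq(0, 350, by = 10))
}
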