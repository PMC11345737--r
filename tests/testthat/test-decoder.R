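# Decoder: preprocessing, lagged designs, ridge fits, CV, evaluation,
# generalization matrices.

test_that("lag specification has the conventional 46 lags at 100 Hz", {
  expect_equal(n_lags(lag_spec(-50, 400, 100)), 46)
  expect_equal(n_lags(lag_spec(0, 0, 100)), 1)
  expect_error(lag_spec(400, -50), "exceed")
})

test_that("average referencing removes common-mode signal", {
  s <- sin((1:2560) / 10)
  raw <- eeg_recording(rbind(s, s, s), 256)
  out <- prepare_eeg(raw, trim_s = 2)
  expect_lt(max(abs(out$data)), 1e-9)
})

test_that("preprocessing trims and resamples to the expected length", {
  raw <- eeg_recording(matrix(rnorm(2 * 512 * 100), 2), 512)
  out <- prepare_eeg(raw)   # 100 s -> trim 2 x 5 s -> 90 s at 100 Hz
  expect_equal(ncol(out$data), 9000)
  expect_equal(out$rate, 100)
  expect_error(prepare_eeg(eeg_recording(matrix(rnorm(2 * 512 * 8), 2), 512)),
               "shorter")
})

test_that("the preprocessing chain attenuates 50 Hz far more than 10 Hz", {
  t <- (1:(512 * 30)) / 512
  mk <- function(f) eeg_recording(rbind(sin(2 * pi * f * t), -sin(2 * pi * f * t)), 512)
  rms50 <- sd(prepare_eeg(mk(50))$data[1, ])
  rms10 <- sd(prepare_eeg(mk(10))$data[1, ])
  expect_gt(20 * log10(rms10 / rms50), 20)
})

test_that("lagged design matches direct indexing and has the right shape", {
  set.seed(21)
  d <- matrix(rnorm(2 * 300), 2)
  rec <- eeg_recording(d, 100)
  X <- build_lag_matrix(rec, lag_spec(-50, 400, 100))
  expect_equal(dim(X), c(300, 93))        # 2 x 46 + intercept
  expect_true(all(X[, 93] == 1))
  lags <- envtrack:::lag_samples(lag_spec(-50, 400, 100))
  # lag +10 ms at 100 Hz = +1 sample, checked against a shifted copy
  col <- which(lags == 1)
  expect_equal(X[1:299, col], d[1, 2:300])
  expect_equal(X[300, col], 0)            # zero padding
  # single-channel, single-lag design is the channel plus intercept
  X0 <- build_lag_matrix(eeg_recording(d[1, , drop = FALSE], 100),
                         lag_spec(0, 0, 100))
  expect_equal(X0[, 1], d[1, ])
  expect_equal(ncol(X0), 2)
})

test_that("ridge fit matches the augmented least-squares oracle", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(50:200, 1); nc <- sample(1:5, 1); nl <- sample(1:10, 1)
    X <- cbind(matrix(rnorm(n * nc * nl), n), 1)
    y <- rnorm(n)
    for (lam in c(0, 1, 1e3)) {
      w <- fit_ridge(X, y, lam)$w
      p <- ncol(X)
      D <- diag(sqrt(lam), p); D[p, p] <- 0
      w_ref <- qr.solve(rbind(X, D), c(y, numeric(p)))
      expect_lt(max(abs(w - w_ref)), 1e-8)
    }
  }
})

test_that("ridge limits behave: perfect regressor and total shrinkage", {
  set.seed(23)
  rec <- eeg_recording(matrix(rnorm(3 * 400), 3), 100)
  X <- build_lag_matrix(rec, lag_spec(0, 90, 100))
  y <- X[, 5]
  f <- fit_ridge(X, y, 0)
  w <- f$w
  expect_equal(w[5], 1, tolerance = 1e-8)
  expect_lt(max(abs(w[-5])), 1e-8)
  expect_equal(cor(drop(X %*% w), y), 1, tolerance = 1e-12)
  # heavy shrinkage leaves only the intercept: prediction collapses to the mean
  fs <- fit_ridge(X, y, 1e12)
  expect_lt(max(abs(fs$w[-ncol(X)])), 1e-6)
  expect_equal(fs$intercept, mean(y), tolerance = 1e-3)
  expect_error(fit_ridge(X, y, -1), "lambda")
})

test_that("decoder weights reshape into the channels x lags kernel", {
  rec <- eeg_recording(matrix(rnorm(2 * 200), 2), 100)
  X <- build_lag_matrix(rec, lag_spec(0, 40, 100))
  f <- fit_ridge(X, rnorm(200), 1)
  expect_equal(dim(f$g), c(2, 5))
  expect_equal(f$g[2, 3], f$w[5 + 3])
})

test_that("cross-validation picks sensible penalties with contiguous folds", {
  env <- quick_envelope(40, seed = 24)
  y <- env$samples
  rec <- eeg_recording(rbind(y, rnorm(length(y))), 100)
  # singleton grid is returned as-is
  cv1 <- cross_validate(env, rec, 4, lambda_grid = 42, spec = lag_spec(0, 100, 100))
  expect_equal(cv1$best_lambda, 42)
  # noiseless identity mapping reconstructs near-perfectly at small lambda
  cv <- cross_validate(env, rec, 4, lambda_grid = 10^seq(-7, -2, length.out = 4),
                       spec = lag_spec(0, 100, 100))
  expect_true(all(cv$mean_val_r >= 0.999))
  # 15-point default grid: finite everywhere
  cv15 <- cross_validate(env, rec, 4, spec = lag_spec(0, 100, 100))
  expect_length(cv15$mean_val_r, 15)
  expect_true(all(is.finite(cv15$mean_val_r)))
  expect_true(cv15$best_lambda %in% cv15$lambda_grid)
  expect_error(cross_validate(env, rec, 1), "folds")
})

test_that("training refits at the selected penalty and group mode uses subject folds", {
  env <- quick_envelope(30, seed = 25)
  cfg <- quick_config()
  k <- make_condition_kernel(3, condition_label("A", "unprocessed"), cfg, 4)
  ee <- synthesize_eeg(env, k, 5, seed = 2)
  dec <- train_decoder(env, ee, "subject", lambda_grid = quick_grid)
  refit <- fit_ridge(build_lag_matrix(ee), env, dec$lambda)
  expect_equal(dec$w, refit$w, tolerance = 1e-12)
  # group mode: one fold per training subject
  envs <- lapply(1:3, function(i) quick_envelope(30, seed = 30 + i))
  eegs <- lapply(1:3, function(i)
    synthesize_eeg(envs[[i]], k, 0, seed = 40 + i))
  g <- train_decoder(envs, eegs, "group", lambda_grid = quick_grid)
  expect_equal(g$training_meta$n_train_subjects, 3)
  expect_s3_class(g$cv, "cv_result")
  expect_error(train_decoder(envs[1], eegs[1], "group"), "2 training subjects")
})

test_that("evaluation windows, consistency and constant-prediction convention hold", {
  env <- quick_envelope(30, seed = 26)
  rec <- eeg_recording(rbind(env$samples, rnorm(length(env$samples))), 100)
  X <- build_lag_matrix(rec, lag_spec(-50, 400, 100))
  dec <- fit_ridge(X, env, 1e-6)
  # evaluating on its own training data: essentially perfect
  expect_gt(evaluate(dec, env, rec, 30)$r, 0.999)
  # explicit truncation equals the window argument
  r1 <- evaluate(dec, env, rec, 10)$r
  rec10 <- eeg_recording(rec$data[, 1:1000], 100)
  env10 <- env_signal(env$samples[1:1000], 100)
  expect_equal(evaluate(dec, env10, rec10, 10)$r, r1, tolerance = 1e-12)
  # all-zero decoder predicts a constant
  dec0 <- dec; dec0$w[] <- 0
  expect_warning(r0 <- evaluate(dec0, env, rec, 30)$r, "constant")
  expect_equal(r0, 0)
  expect_error(evaluate(dec, env, eeg_recording(rec$data[1, , drop = FALSE], 100)),
               "channel")
})

test_that("a no-effect noiseless cohort yields a flat generalization matrix", {
  cfg <- quick_config(n_subjects = 1, trial_duration_s = 30, test_duration_s = 15,
                      n_channels = 4, snr_db = Inf, language_gain = 1,
                      degradation_shape_jitter = 0, kernel_family = "impulse",
                      seed = 55)
  co <- make_cohort(cfg, keep_audio = FALSE)
  gm <- generalization_matrix(co, "subject", lambda_grid = quick_grid,
                              test_window_s = 15)
  expect_equal(nrow(gm), 36)
  expect_lt(max(gm$r) - min(gm$r), 0.02)
  expect_true(all(gm$r >= -1 & gm$r <= 1))
})
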