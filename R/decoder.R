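# Backward stimulus reconstruction: s_hat(t) = sum_n sum_tau r(t + tau, n) g(tau, n).
# Ridge decoders are fit on lagged multichannel designs via the normal
# equations; the lagged covariance is computed once per dataset and
# refactorized per lambda, which is what makes the permutation null loop and
# leave-one-subject-out training affordable.

#' Decoder lag specification
#'
#' Post-stimulus lags applied to the neural response, default -50 to 400 ms
#' at 100 Hz (46 lags).
#'
#' @param tmin_ms,tmax_ms lag range in milliseconds (`tmin_ms <= tmax_ms`;
#'   equal values give a single lag).
#' @param rate sampling rate of the decoded signals in Hz.
#' @return object of class `lag_spec`.
#' @export
lag_spec <- function(tmin_ms = -50, tmax_ms = 400, rate = 100) {
  if (tmin_ms > tmax_ms) stop_invalid("tmin_ms must not exceed tmax_ms")
  structure(list(tmin_ms = tmin_ms, tmax_ms = tmax_ms, rate = rate),
            class = "lag_spec")
}

lag_samples <- function(spec) {
  seq(round(spec$tmin_ms * spec$rate / 1000),
      round(spec$tmax_ms * spec$rate / 1000))
}

#' Number of lags in a lag specification
#' @param spec a [lag_spec()].
#' @return integer lag count.
#' @export
n_lags <- function(spec) length(lag_samples(spec))

#' Preprocess raw EEG for decoding
#'
#' Average-references the channels, resamples to a working rate, applies
#' zero-phase 4th-order Butterworth highpass then lowpass filters, trims the
#' first and last `trim_s` seconds, and resamples to the decoding rate.
#'
#' @param raw an [eeg_recording()]; `raw$rate >= 2 * lp_hz` required.
#' @param hp_hz,lp_hz highpass and lowpass corners in Hz.
#' @param work_rate intermediate processing rate in Hz.
#' @param out_rate output (decoding) rate in Hz.
#' @param trim_s seconds removed from each end after filtering.
#' @return preprocessed [eeg_recording()] at `out_rate`.
#' @export
prepare_eeg <- function(raw, hp_hz = 0.5, lp_hz = 40, work_rate = 256,
                        out_rate = 100, trim_s = 5) {
  stopifnot(inherits(raw, "eeg_recording"))
  if (raw$rate < 2 * lp_hz)
    stop_invalid("recording rate must be at least twice the lowpass corner")
  if (ncol(raw$data) / raw$rate <= 2 * trim_s)
    stop_invalid("recording shorter than twice the trim length")
  d <- sweep(raw$data, 2, colMeans(raw$data))        # average reference
  proc <- lapply(seq_len(nrow(d)), function(ch) {
    x <- resample_signal(d[ch, ], raw$rate, work_rate)
    x <- butter_filtfilt(x, 4, hp_hz, work_rate, "high")
    x <- butter_filtfilt(x, 4, lp_hz, work_rate, "low")
    nt <- round(trim_s * work_rate)
    x <- x[(nt + 1):(length(x) - nt)]
    resample_signal(x, work_rate, out_rate)
  })
  eeg_recording(do.call(rbind, proc), out_rate, raw$channel_labels)
}

#' Build the lagged design matrix
#'
#' Row `t`, column `(n, tau)` holds `r(t + tau, n)`; out-of-range samples
#' are zero padded and an all-ones intercept column is appended last.
#'
#' @param resp an [eeg_recording()] at `spec$rate`.
#' @param spec a [lag_spec()].
#' @return samples x (channels * lags + 1) matrix with attributes
#'   `lag_spec`, `n_channels`, `channel_labels`.
#' @export
build_lag_matrix <- function(resp, spec = lag_spec()) {
  stopifnot(inherits(resp, "eeg_recording"), inherits(spec, "lag_spec"))
  if (resp$rate != spec$rate) stop_invalid("response rate must match lag_spec rate")
  if (ncol(resp$data) < 1) stop_invalid("empty recording")
  X <- lag_design_cpp(resp$data, as.integer(lag_samples(spec)))
  attr(X, "lag_spec") <- spec
  attr(X, "n_channels") <- nrow(resp$data)
  attr(X, "channel_labels") <- resp$channel_labels
  X
}

as_target <- function(target) {
  if (inherits(target, "env_signal")) target$samples else as.numeric(target)
}

# Solve (A + lambda * diag(pen)) w = b; eigen-based minimum-norm fallback for
# singular systems at lambda = 0.
ridge_solve <- function(A, b, lambda, pen) {
  Ar <- A + diag(lambda * pen, nrow(A))
  w <- tryCatch(chol2inv(chol(Ar)) %*% b, error = function(e) NULL)
  if (is.null(w)) {
    warning("rank-deficient design; returning the minimum-norm solution")
    e <- eigen(Ar, symmetric = TRUE)
    tol <- max(e$values) * 1e-12
    inv <- ifelse(e$values > tol, 1 / e$values, 0)
    w <- e$vectors %*% (inv * (t(e$vectors) %*% b))
  }
  drop(w)
}

#' Fit a ridge decoder on a lagged design
#'
#' Minimizes `||target - design w||^2 + lambda ||w||^2` with the intercept
#' column unpenalized, via the normal equations on the lagged covariance.
#' No eigenvalue normalization is applied to `lambda`; the convention is
#' fixed and documented.
#'
#' @param design design matrix from [build_lag_matrix()] (or any matrix
#'   whose last column is the intercept).
#' @param target the envelope to reconstruct ([env_signal()] or numeric).
#' @param lambda ridge penalty, >= 0.
#' @return object of class `decoder_weights`: full weight vector `w`
#'   (intercept last), the channels x lags matrix `g` and `intercept` when
#'   the design carries lag metadata, plus `lambda` and `training_meta`.
#' @export
fit_ridge <- function(design, target, lambda) {
  y <- as_target(target)
  if (nrow(design) != length(y))
    stop_invalid("design rows must match target length")
  if (!is.numeric(lambda) || lambda < 0) stop_invalid("lambda must be >= 0")
  p <- ncol(design)
  pen <- rep(1, p); pen[p] <- 0                     # intercept unpenalized
  w <- ridge_solve(crossprod(design), crossprod(design, y), lambda, pen)
  spec <- attr(design, "lag_spec")
  n_ch <- attr(design, "n_channels")
  g <- NULL
  if (!is.null(spec) && !is.null(n_ch)) {
    L <- n_lags(spec)
    g <- matrix(w[seq_len(n_ch * L)], nrow = n_ch, ncol = L, byrow = TRUE)
  }
  structure(list(w = w, g = g, intercept = w[p], lag_spec = spec,
                 lambda = lambda,
                 n_channels = n_ch %||% NA_integer_,
                 channel_labels = attr(design, "channel_labels"),
                 training_meta = list()),
            class = "decoder_weights")
}

#' @export
print.decoder_weights <- function(x, ...) {
  cat(sprintf("<decoder_weights> %s channels x %s lags, lambda = %g\n",
              x$n_channels, if (is.null(x$g)) length(x$w) - 1 else ncol(x$g),
              x$lambda))
  invisible(x)
}

#' Default ridge penalty grid
#'
#' 15 logarithmically spaced values spanning 1e-7 to 1e7 (integer decades).
#'
#' @return numeric vector of penalties.
#' @export
default_lambda_grid <- function() 10^seq(-7, 7, length.out = 15)

# Contiguous fold assignment over n samples.
fold_bounds <- function(n, k) {
  edges <- round(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) seq(edges[i] + 1, edges[i + 1]))
}

# Sufficient statistics for one dataset: XtX, Xty per fold plus totals.
design_stats <- function(X, y, folds) {
  per <- lapply(folds, function(idx) {
    Xf <- X[idx, , drop = FALSE]
    list(idx = idx, XtX = crossprod(Xf), Xty = crossprod(Xf, y[idx]))
  })
  list(per = per,
       XtX = Reduce(`+`, lapply(per, `[[`, "XtX")),
       Xty = Reduce(`+`, lapply(per, `[[`, "Xty")))
}

#' Cross-validate the ridge penalty
#'
#' Splits the data into `k_folds` contiguous, non-overlapping time folds;
#' for each penalty trains on k-1 folds and scores Pearson r on the held-out
#' fold; `best_lambda` maximizes the fold-mean validation r, with ties
#' broken toward heavier regularization.
#'
#' @param stim target envelope ([env_signal()] or numeric).
#' @param resp an [eeg_recording()].
#' @param k_folds number of contiguous folds (>= 2).
#' @param lambda_grid candidate penalties.
#' @param spec a [lag_spec()].
#' @return object of class `cv_result`: `lambda_grid`, `mean_val_r`,
#'   `best_lambda`.
#' @export
cross_validate <- function(stim, resp, k_folds = 4,
                           lambda_grid = default_lambda_grid(),
                           spec = lag_spec()) {
  if (k_folds < 2) stop_invalid("need at least 2 folds")
  X <- build_lag_matrix(resp, spec)
  y <- as_target(stim)
  if (nrow(X) != length(y)) stop_invalid("stimulus and response lengths differ")
  if (nrow(X) < 2 * k_folds) stop_invalid("too few samples for the fold count")
  st <- design_stats(X, y, fold_bounds(nrow(X), k_folds))
  pen <- rep(1, ncol(X)); pen[ncol(X)] <- 0
  val <- vapply(lambda_grid, function(lam) {
    mean(vapply(st$per, function(f) {
      w <- ridge_solve(st$XtX - f$XtX, st$Xty - f$Xty, lam, pen)
      pearson_r(drop(X[f$idx, , drop = FALSE] %*% w), y[f$idx],
                warn_constant = FALSE)
    }, 1.0))
  }, 1.0)
  best <- max(lambda_grid[val == max(val)])
  structure(list(lambda_grid = lambda_grid, mean_val_r = val,
                 best_lambda = best),
            class = "cv_result")
}

#' Train a decoder with cross-validated regularization
#'
#' Subject mode: one recording, penalty chosen by `k_folds` contiguous-fold
#' cross-validation, final weights refit on all training data at the best
#' penalty. Group mode: per-subject recordings are pooled and
#' cross-validation uses one fold per training subject (leave-one-subject-
#' out over the training set).
#'
#' @param stim an [env_signal()] (subject mode) or list of envelopes (group
#'   mode).
#' @param resp an [eeg_recording()] or list of recordings matching `stim`.
#' @param mode `"subject"` or `"group"`.
#' @param spec a [lag_spec()].
#' @param k_folds folds for subject-mode cross-validation.
#' @param lambda_grid candidate penalties.
#' @return a `decoder_weights` object with the `cv_result` attached as `$cv`
#'   and training metadata in `$training_meta`.
#' @export
train_decoder <- function(stim, resp, mode = c("subject", "group"),
                          spec = lag_spec(), k_folds = 4,
                          lambda_grid = default_lambda_grid()) {
  mode <- match.arg(mode)
  if (mode == "subject") {
    cv <- cross_validate(stim, resp, k_folds, lambda_grid, spec)
    dec <- fit_ridge(build_lag_matrix(resp, spec), stim, cv$best_lambda)
    dec$cv <- cv
    dec$training_meta <- list(mode = "subject")
    return(dec)
  }
  if (!is.list(stim) || !is.list(resp) || length(stim) != length(resp))
    stop_invalid("group mode needs matching lists of envelopes and recordings")
  m <- length(stim)
  if (m < 2) stop_invalid("group mode needs at least 2 training subjects")
  Xs <- lapply(resp, build_lag_matrix, spec = spec)
  ys <- lapply(stim, as_target)
  XtX <- lapply(Xs, crossprod)
  Xty <- Map(function(X, y) crossprod(X, y), Xs, ys)
  A <- Reduce(`+`, XtX); b <- Reduce(`+`, Xty)
  pen <- rep(1, ncol(A)); pen[ncol(A)] <- 0
  val <- vapply(lambda_grid, function(lam) {
    mean(vapply(seq_len(m), function(j) {
      w <- ridge_solve(A - XtX[[j]], b - Xty[[j]], lam, pen)
      pearson_r(drop(Xs[[j]] %*% w), ys[[j]], warn_constant = FALSE)
    }, 1.0))
  }, 1.0)
  best <- max(lambda_grid[val == max(val)])
  w <- ridge_solve(A, b, best, pen)
  spec_attr <- attr(Xs[[1]], "lag_spec"); n_ch <- attr(Xs[[1]], "n_channels")
  L <- n_lags(spec_attr)
  dec <- structure(
    list(w = w, g = matrix(w[seq_len(n_ch * L)], n_ch, L, byrow = TRUE),
         intercept = w[length(w)], lag_spec = spec_attr, lambda = best,
         n_channels = n_ch, channel_labels = attr(Xs[[1]], "channel_labels"),
         training_meta = list(mode = "group", n_train_subjects = m),
         cv = structure(list(lambda_grid = lambda_grid, mean_val_r = val,
                             best_lambda = best), class = "cv_result")),
    class = "decoder_weights")
  dec
}

#' Reconstruct the envelope and score decoding accuracy
#'
#' Applies the decoder to the first `test_window_s` seconds of the test
#' recording and correlates the reconstruction with the test envelope.
#'
#' @param decoder a `decoder_weights`.
#' @param stim test-segment envelope.
#' @param resp test-segment [eeg_recording()] with the decoder's channels.
#' @param test_window_s evaluation window in seconds (default 60).
#' @return object of class `decoding_result`: list with `r`, `lambda`,
#'   `n_samples`.
#' @export
evaluate <- function(decoder, stim, resp, test_window_s = 60) {
  stopifnot(inherits(decoder, "decoder_weights"), inherits(resp, "eeg_recording"))
  if (!is.null(decoder$g) && nrow(resp$data) != nrow(decoder$g))
    stop_invalid("channel count does not match the decoder")
  y <- as_target(stim)
  n <- min(length(y), ncol(resp$data), round(test_window_s * resp$rate))
  y <- y[seq_len(n)]
  rec <- eeg_recording(resp$data[, seq_len(n), drop = FALSE], resp$rate,
                       resp$channel_labels)
  X <- build_lag_matrix(rec, decoder$lag_spec %||% lag_spec(rate = resp$rate))
  s_hat <- drop(X %*% decoder$w)
  structure(list(r = pearson_r(s_hat, y), lambda = decoder$lambda,
                 n_samples = n, reconstruction = s_hat),
            class = "decoding_result")
}

#' Train x test condition generalization matrices
#'
#' Subject mode: per subject, a decoder is trained on each condition's
#' training segment and evaluated on every condition's held-out test
#' window (6 x 6 results per subject). Group mode: for each held-out
#' subject, decoders are trained on the pooled training data of the other
#' subjects (penalty cross-validated over one fold per training subject)
#' and evaluated on the held-out subject's test windows.
#'
#' @param cohort a `synthetic_cohort` from [make_cohort()] (or an object of
#'   the same shape built from files).
#' @param mode `"subject"` or `"group"`.
#' @param spec a [lag_spec()].
#' @param k_folds subject-mode cross-validation folds.
#' @param lambda_grid candidate penalties.
#' @param test_window_s evaluation window in seconds.
#' @return data.frame with columns mode, subject, trained_language,
#'   trained_degradation, test_language, test_degradation, lambda, r.
#' @export
generalization_matrix <- function(cohort, mode = c("subject", "group"),
                                  spec = lag_spec(), k_folds = 4,
                                  lambda_grid = default_lambda_grid(),
                                  test_window_s = 60) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  conds <- cohort$conditions
  n_sub <- length(cohort$cells)
  if (mode == "group" && n_sub < 2)
    stop_invalid("group mode needs at least 2 subjects")
  rows <- list()
  add_row <- function(subject, tc, ec, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mode = mode, subject = subject,
      trained_language = tc$language, trained_degradation = tc$degradation,
      test_language = ec$language, test_degradation = ec$degradation,
      lambda = res$lambda, r = res$r, stringsAsFactors = FALSE)
  }
  if (mode == "subject") {
    for (s in seq_len(n_sub)) {
      for (tc in conds) {
        cell <- cohort$cells[[s]][[condition_id(tc)]]
        if (is.null(cell)) stop_invalid("missing cohort cell")
        dec <- train_decoder(cell$train_env, cell$train_eeg, "subject",
                             spec, k_folds, lambda_grid)
        for (ec in conds) {
          tcell <- cohort$cells[[s]][[condition_id(ec)]]
          add_row(s, tc, ec, evaluate(dec, tcell$test_env, tcell$test_eeg,
                                      test_window_s))
        }
      }
    }
  } else {
    for (s in seq_len(n_sub)) {
      others <- setdiff(seq_len(n_sub), s)
      for (tc in conds) {
        cid <- condition_id(tc)
        dec <- train_decoder(lapply(others, function(j) cohort$cells[[j]][[cid]]$train_env),
                             lapply(others, function(j) cohort$cells[[j]][[cid]]$train_eeg),
                             "group", spec, lambda_grid = lambda_grid)
        for (ec in conds) {
          tcell <- cohort$cells[[s]][[condition_id(ec)]]
          add_row(s, tc, ec, evaluate(dec, tcell$test_env, tcell$test_eeg,
                                      test_window_s))
        }
      }
    }
  }
  do.call(rbind, rows)
}
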