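# Segment-shuffle permutation null for decoder accuracy: cut the envelope
# into ~3 s chunks at low-amplitude points, permute them with no chunk left
# in place (a derangement), rejoin smoothly, and re-train/re-test the
# decoder against the unmodified neural response.

#' Shuffle specification
#'
#' @param chunk_s nominal segment length in seconds (~3).
#' @param join_ms span of the smooth join bridging adjacent segments, in
#'   milliseconds.
#' @param seed integer seed for the permutation stream.
#' @param derange if `TRUE` (default) segment orders are uniform random
#'   derangements (no segment keeps its index); if `FALSE` only the identity
#'   permutation is excluded.
#' @return object of class `shuffle_spec`.
#' @export
shuffle_spec <- function(chunk_s = 3, join_ms = 50, seed = 1, derange = TRUE) {
  if (chunk_s <= join_ms / 1000) stop_invalid("chunk_s must exceed the join span")
  structure(list(chunk_s = chunk_s, join_ms = join_ms, seed = as.integer(seed),
                 derange = derange),
            class = "shuffle_spec")
}

# Uniform random derangement by rejection; n = 2 has a single derangement.
random_derangement <- function(n) {
  if (n < 2) stop_invalid("need at least 2 segments")
  if (n == 2) return(c(2L, 1L))
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

# Cut points: the crossing of the envelope's own mean nearest each multiple
# of chunk_s (the envelope is nonnegative, so its mean plays the role of
# zero). Falls back to the nominal grid where no crossing exists nearby.
segment_cuts <- function(x, rate, chunk_s) {
  n <- length(x)
  n_seg <- max(2L, round(n / (chunk_s * rate)))
  nominal <- round(seq_len(n_seg - 1) * n / n_seg)
  m <- mean(x)
  crossings <- which((x[-n] - m) * (x[-1] - m) <= 0)
  half <- floor(chunk_s * rate / 2)
  cuts <- vapply(nominal, function(g) {
    near <- crossings[abs(crossings - g) <= half]
    if (length(near) == 0) g else near[which.min(abs(near - g))]
  }, 1.0)
  cuts <- sort(unique(pmin(pmax(cuts, 1), n - 1)))
  c(0, cuts, n)
}

#' Segment-shuffle an envelope
#'
#' Cuts the envelope at mean-crossings nearest multiples of `chunk_s`,
#' permutes the segments by a uniform random derangement (every segment
#' moves), and re-concatenates, bridging each junction with monotone cubic
#' interpolation over `join_ms` so joins are continuous and nonnegative.
#' The output has exactly the input length and, outside the join windows,
#' exactly the input's sample values (reordered).
#'
#' @param env an [env_signal()] at least two chunks long.
#' @param spec a [shuffle_spec()].
#' @return shuffled [env_signal()].
#' @export
shuffle_envelope <- function(env, spec = shuffle_spec()) {
  stopifnot(inherits(env, "env_signal"), inherits(spec, "shuffle_spec"))
  x <- env$samples
  if (length(x) < 2 * spec$chunk_s * env$rate)
    stop_invalid("envelope shorter than two chunks")
  bounds <- segment_cuts(x, env$rate, spec$chunk_s)
  n_seg <- length(bounds) - 1
  segs <- lapply(seq_len(n_seg),
                 function(i) x[(bounds[i] + 1):bounds[i + 1]])
  ord <- with_seed(spec$seed, {
    if (spec$derange) random_derangement(n_seg)
    else { repeat { p <- sample.int(n_seg); if (any(p != seq_len(n_seg))) break }; p }
  })
  out <- unlist(segs[ord], use.names = FALSE)
  # smooth each internal junction over the join span
  w <- max(2L, round(spec$join_ms / 1000 * env$rate))
  pos <- cumsum(vapply(segs[ord], length, 1L))
  for (j in pos[-length(pos)]) {
    i0 <- max(1L, j - floor(w / 2)); i1 <- min(length(out), j + ceiling(w / 2))
    if (i1 - i0 >= 2) {
      f <- splinefun(c(i0, i1), c(out[i0], out[i1]), method = "monoH.FC")
      out[(i0 + 1):(i1 - 1)] <- f((i0 + 1):(i1 - 1))
    }
  }
  env_signal(out, env$rate)
}

#' Permutation null distribution for a decoder
#'
#' Re-trains and re-tests the decoder `n_perm` times with segment-shuffled
#' training and test envelopes against the unmodified neural responses,
#' at the observed decoder's penalty. The lagged covariance of each design
#' is computed and factorized once, so each permutation costs only one
#' cross-product and triangular solve.
#'
#' @param train_env,train_resp training envelope and EEG.
#' @param test_env,test_resp held-out envelope and EEG.
#' @param lambda ridge penalty of the observed decoder.
#' @param spec_lag a [lag_spec()].
#' @param spec_shuffle a [shuffle_spec()]; permutation `i` uses the stream
#'   seeded by `derive_seed(spec_shuffle$seed, "perm", i)`.
#' @param n_perm number of permutations (>= 1; the study convention is 1000).
#' @param test_window_s evaluation window in seconds.
#' @return object of class `null_distribution`: `null_r` (length `n_perm`),
#'   `observed_r`, `n_perm`, `lambda`; percentile rank and tier are filled
#'   in by [significance()].
#' @export
null_distribution <- function(train_env, train_resp, test_env, test_resp,
                              lambda, spec_lag = lag_spec(),
                              spec_shuffle = shuffle_spec(), n_perm = 1000,
                              test_window_s = 60) {
  if (n_perm < 1) stop_invalid("need at least one permutation")
  X <- build_lag_matrix(train_resp, spec_lag)
  y <- as_target(train_env)
  if (nrow(X) != length(y)) stop_invalid("training lengths differ")
  p <- ncol(X)
  pen <- rep(1, p); pen[p] <- 0
  R <- chol(crossprod(X) + diag(lambda * pen, p))
  solve_w <- function(target)
    backsolve(R, backsolve(R, crossprod(X, target), transpose = TRUE))
  n_test <- min(length(as_target(test_env)), ncol(test_resp$data),
                round(test_window_s * test_resp$rate))
  Xt <- build_lag_matrix(
    eeg_recording(test_resp$data[, seq_len(n_test), drop = FALSE],
                  test_resp$rate, test_resp$channel_labels), spec_lag)
  yt_full <- as_target(test_env)
  score <- function(y_train, y_test)
    pearson_r(drop(Xt %*% solve_w(y_train)), y_test[seq_len(n_test)],
              warn_constant = FALSE)
  observed <- score(y, yt_full)
  null_r <- vapply(seq_len(n_perm), function(i) {
    si <- derive_seed(spec_shuffle$seed, "perm", i)
    sh_tr <- shuffle_envelope(train_env,
                              shuffle_spec(spec_shuffle$chunk_s,
                                           spec_shuffle$join_ms, si,
                                           spec_shuffle$derange))
    sh_te <- shuffle_envelope(test_env,
                              shuffle_spec(spec_shuffle$chunk_s,
                                           spec_shuffle$join_ms,
                                           derive_seed(si, "test"),
                                           spec_shuffle$derange))
    score(sh_tr$samples, sh_te$samples)
  }, 1.0)
  significance(structure(list(null_r = null_r, observed_r = observed,
                              n_perm = n_perm, lambda = lambda,
                              percentile_rank = NA_real_, tier = NA_character_),
                         class = "null_distribution"))
}

#' Percentile rank and significance tier of an observed decoder
#'
#' The percentile rank is the midrank position of the observed accuracy in
#' its null distribution; the tier follows the convention that an accuracy
#' exceeding the 95th/99th/99.9th percentile of the null is significant at
#' p < .05 / .01 / .001.
#'
#' @param null a `null_distribution`.
#' @return the object with `percentile_rank` in [0, 100] and `tier` in
#'   `{"ns", "p<.05", "p<.01", "p<.001"}` filled in.
#' @export
significance <- function(null) {
  stopifnot(inherits(null, "null_distribution"))
  if (length(null$null_r) == 0) stop_invalid("empty null distribution")
  nr <- null$null_r; obs <- null$observed_r
  rank <- 100 * (sum(nr < obs) + 0.5 * sum(nr == obs)) / length(nr)
  null$percentile_rank <- rank
  null$tier <- if (rank > 99.9) "p<.001" else if (rank > 99) "p<.01" else
    if (rank > 95) "p<.05" else "ns"
  null
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> n_perm = %d, observed r = %.4f, rank = %.1f (%s)\n",
              x$n_perm, x$observed_r, x$percentile_rank, x$tier))
  invisible(x)
}

#' Significance tier from a percentile rank
#' @param rank percentile rank in [0, 100].
#' @return tier label.
#' @export
tier_of <- function(rank) {
  ifelse(rank > 99.9, "p<.001",
         ifelse(rank > 99, "p<.01", ifelse(rank > 95, "p<.05", "ns")))
}
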