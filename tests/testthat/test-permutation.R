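# Segment shuffling and permutation-null significance.

test_that("two segments are forced to swap", {
  e <- env_signal(abs(rnorm(700)) + 0.1, 100)
  sh <- shuffle_envelope(e, shuffle_spec(3, 50, seed = 1))
  # with ~2 segments the only derangement is the swap: the tail of the
  # original should now lead
  expect_length(sh$samples, 700)
  expect_false(isTRUE(all.equal(sh$samples, e$samples)))
})

test_that("a 60 s envelope at 3 s chunks yields about 20 segments", {
  e <- quick_envelope(60, seed = 41)
  cuts <- envtrack:::segment_cuts(e$samples, 100, 3)
  expect_lte(abs((length(cuts) - 1) - 20), 2)
})

test_that("shuffles derange segments, conserve length and preserve values outside joins", {
  e <- quick_envelope(30, seed = 42)     # ~10 segments
  n <- length(e$samples)
  for (seed in 1:100) {
    sp <- shuffle_spec(3, 50, seed = seed)
    sh <- shuffle_envelope(e, sp)
    expect_length(sh$samples, n)
    # reconstruct the permutation actually applied and check it is a derangement
    cuts <- envtrack:::segment_cuts(e$samples, 100, 3)
    segs <- lapply(seq_len(length(cuts) - 1),
                   function(i) e$samples[(cuts[i] + 1):cuts[i + 1]])
    ord <- envtrack:::with_seed(seed, envtrack:::random_derangement(length(segs)))
    expect_true(all(ord != seq_along(ord)))
    # outside the join windows the sample multiset is untouched
    w <- round(0.05 * 100)
    pos <- cumsum(vapply(segs[ord], length, 1L))
    joined <- unlist(lapply(pos[-length(pos)], function(j)
      max(1, j - w):min(n, j + w)))
    expect_identical(sort(sh$samples[-joined]),
                     sort(unlist(segs[ord], use.names = FALSE)[-joined]))
  }
  expect_error(shuffle_envelope(env_signal(abs(rnorm(100)), 100),
                                shuffle_spec(3, 50, 1)), "shorter")
})

test_that("shuffled output is nonnegative and continuous at joins", {
  e <- quick_envelope(30, seed = 43)
  sh <- shuffle_envelope(e, shuffle_spec(3, 50, seed = 9))
  expect_true(all(sh$samples >= 0))
  expect_lt(max(abs(diff(sh$samples))), 10 * max(abs(diff(e$samples))))
})

test_that("percentile ranks and tiers follow the observed position in the null", {
  base <- list(null_r = seq(0.001, 1, length.out = 1000) / 10, n_perm = 1000,
               lambda = 1, percentile_rank = NA_real_, tier = NA_character_)
  above <- significance(structure(modifyList(base, list(observed_r = 1)),
                                  class = "null_distribution"))
  expect_equal(above$percentile_rank, 100)
  expect_equal(above$tier, "p<.001")
  at96 <- significance(structure(modifyList(base, list(observed_r = 0.09605)),
                                 class = "null_distribution"))
  expect_gt(at96$percentile_rank, 95.5)
  expect_lt(at96$percentile_rank, 97)
  expect_equal(at96$tier, "p<.05")
  atmed <- significance(structure(modifyList(base, list(observed_r = median(base$null_r))),
                                  class = "null_distribution"))
  expect_equal(atmed$percentile_rank, 50, tolerance = 0.1)
  expect_equal(atmed$tier, "ns")
})

test_that("null distributions are total, finite and deterministic", {
  env <- quick_envelope(40, seed = 44)
  cell <- split_cell(env, synthesize_eeg(env, impulse_kernel(3), 0, seed = 4), 30)
  nd <- null_distribution(cell$train_env, cell$train_eeg, cell$test_env,
                          cell$test_eeg, lambda = 100, n_perm = 25,
                          spec_shuffle = shuffle_spec(seed = 5),
                          test_window_s = 10)
  expect_length(nd$null_r, 25)
  expect_true(all(is.finite(nd$null_r)))
  expect_true(nd$tier %in% c("ns", "p<.05", "p<.01", "p<.001"))
  nd2 <- null_distribution(cell$train_env, cell$train_eeg, cell$test_env,
                           cell$test_eeg, lambda = 100, n_perm = 25,
                           spec_shuffle = shuffle_spec(seed = 5),
                           test_window_s = 10)
  expect_identical(nd$null_r, nd2$null_r)
  expect_error(null_distribution(cell$train_env, cell$train_eeg, cell$test_env,
                                 cell$test_eeg, lambda = 100, n_perm = 0),
               "permutation")
})

test_that("a strongly driven cell beats its entire null", {
  env <- quick_envelope(60, seed = 45)
  cfg <- quick_config()
  k <- make_condition_kernel(8, condition_label("A", "unprocessed"), cfg, 6)
  cell <- split_cell(env, synthesize_eeg(env, k, 10, seed = 6), 40)
  dec <- train_decoder(cell$train_env, cell$train_eeg, "subject",
                       lambda_grid = quick_grid)
  nd <- null_distribution(cell$train_env, cell$train_eeg, cell$test_env,
                          cell$test_eeg, lambda = dec$lambda, n_perm = 200,
                          spec_shuffle = shuffle_spec(seed = 7),
                          test_window_s = 20)
  expect_gt(nd$observed_r, max(nd$null_r))
  expect_equal(nd$tier, "p<.001")
})
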