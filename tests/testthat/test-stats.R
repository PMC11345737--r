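# Concordance, robust dispersion, bootstrap, scaled differences, tier tables.

brute_force_w <- function(R) {
  # direct evaluation of the defining formula on a matrix of rankings
  R <- t(apply(R, 1, rank))
  m <- nrow(R); k <- ncol(R)
  S <- sum((colSums(R) - mean(colSums(R)))^2)
  Tc <- sum(apply(R, 1, function(r) { tt <- table(r); sum(tt^3 - tt) }))
  12 * S / (m^2 * (k^3 - k) - m * Tc)
}

test_that("Kendall's W is 1 for identical rankings and 0 for a reversed pair", {
  R <- rbind(1:6, 1:6, 1:6)
  expect_equal(kendalls_w(R), 1)
  # two untied reversed rankings: W = (rho + 1) / 2 with rho = -1
  expect_equal(kendalls_w(rbind(1:6, 6:1)), 0, tolerance = 1e-12)
  expect_error(kendalls_w(matrix(1:6, 1)), "raters")
})

test_that("Kendall's W matches brute force on random tables, with and without ties", {
  set.seed(61)
  for (i in 1:200) {
    m <- sample(2:5, 1); k <- sample(3:7, 1)
    R <- matrix(sample(1:4, m * k, replace = TRUE) + rnorm(m * k, 0, 0.01), m, k)
    if (i %% 2 == 0) R <- round(R)        # force ties half the time
    w <- kendalls_w(R)
    expect_gte(w, 0); expect_lte(w, 1 + 1e-12)
    expect_equal(w, brute_force_w(R), tolerance = 1e-12)
  }
})

test_that("unscaled MAD matches hand computation and its invariances", {
  expect_equal(mad_raw(c(1, 2, 3, 4, 5)), 1)
  expect_equal(mad_raw(rep(7, 10)), 0)
  set.seed(62)
  x <- rnorm(50)
  expect_equal(mad_raw(x + 100), mad_raw(x), tolerance = 1e-12)
  expect_equal(mad_raw(3 * x), 3 * mad_raw(x), tolerance = 1e-12)
  expect_error(mad_raw(numeric(0)), "empty")
})

test_that("bootstrap intervals are deterministic, degenerate-safe and cover the estimate", {
  expect_warning(ci0 <- bootstrap_ci(rep(2, 5), mean, 100, seed = 1), "degenerate")
  expect_equal(unname(ci0), c(2, 2))
  set.seed(63)
  covered <- vapply(1:100, function(i) {
    x <- rnorm(30)
    ci <- bootstrap_ci(x, mean, 200, seed = i)
    ci["lo"] <= mean(x) && mean(x) <= ci["hi"]
  }, TRUE)
  expect_gte(mean(covered), 0.99)
  x <- rnorm(20)
  expect_identical(bootstrap_ci(x, mean, 500, seed = 9),
                   bootstrap_ci(x, mean, 500, seed = 9))
})

test_that("scaled differences reproduce hand cases and the paired t null", {
  s <- scaled_difference(c(0.2), c(0.14))
  expect_equal(s$values, 0.3, tolerance = 1e-12)
  id <- scaled_difference(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(id$mean, 0)
  expect_warning(dr <- scaled_difference(c(0.2, 0), c(0.1, 0.1)), "dropped")
  expect_equal(dr$n_dropped, 1)
  expect_error(scaled_difference(1:3, 1:2), "length")
  x <- c(0.1, 0.25, 0.4)
  pt <- paired_t(x, x)
  expect_equal(pt$t, 0)
  expect_equal(pt$p, 1)
})

test_that("tier proportions partition to one and extremes behave", {
  nulls <- expand.grid(mode = "subject", subject = 1:8,
                       language = c("A", "B"),
                       degradation = c("unprocessed", "vocoded"),
                       stringsAsFactors = FALSE)
  nulls$percentile_rank <- 100
  nulls$tier <- "p<.001"
  tab <- significance_table(nulls, n_boot = 100)
  expect_true(all(abs(tab$prop_ns + tab$prop_05 + tab$prop_01 + tab$prop_001 - 1) < 1e-12))
  expect_true(all(tab$prop_001 == 1))
  expect_true(all(tab$mad_rank == 0))
  # mixed ranks still partition
  set.seed(64)
  nulls$percentile_rank <- runif(nrow(nulls), 0, 100)
  nulls$tier <- tier_of(nulls$percentile_rank)
  tab2 <- significance_table(nulls, n_boot = 100)
  expect_true(all(abs(tab2$prop_ns + tab2$prop_05 + tab2$prop_01 + tab2$prop_001 - 1) < 1e-12))
  expect_error(significance_table(data.frame()), "non-empty")
})
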