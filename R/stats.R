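# Descriptive comparison layer: concordance between decoding modes, scaled
# accuracy differences, robust dispersion of percentile ranks, bootstrap
# intervals, and significance-tier proportion tables.

#' Kendall's coefficient of concordance W
#'
#' `W = 12 S / (m^2 (k^3 - k) - m T)` where `S` is the sum of squared
#' deviations of the item rank sums and `T` the standard tie correction
#' `sum(t^3 - t)` over tied groups in each rater's ranking. Rows of the
#' input are ranked internally with midranks, so either raw scores or ranks
#' may be supplied.
#'
#' @param rankings m x k matrix: m raters scoring the same k items.
#' @return W in [0, 1].
#' @export
kendalls_w <- function(rankings) {
  rankings <- as.matrix(rankings)
  m <- nrow(rankings); k <- ncol(rankings)
  if (m < 2 || k < 2) stop_invalid("need at least 2 raters and 2 items")
  if (!all(is.finite(rankings))) stop_invalid("rankings must be finite")
  R <- t(apply(rankings, 1, rank))
  S <- sum((colSums(R) - m * (k + 1) / 2)^2)
  Tcorr <- sum(apply(R, 1, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  denom <- m^2 * (k^3 - k) - m * Tcorr
  if (denom <= 0) return(1)        # all items tied within every rater
  12 * S / denom
}

#' Median absolute deviation, unscaled
#'
#' `median(|x - median(x)|)` with no consistency constant, so the result
#' stays in the units of the input (the convention for reporting dispersion
#' of percentile ranks).
#'
#' @param values non-empty numeric vector.
#' @return unscaled MAD.
#' @export
mad_raw <- function(values) {
  if (length(values) == 0) stop_invalid("empty input")
  median(abs(values - median(values)))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples `values` with replacement `n_boot` times, applies `statistic`,
#' and returns the percentile interval at `level`. Deterministic per seed.
#'
#' @param values numeric vector, length >= 2.
#' @param statistic function of a numeric vector returning a scalar.
#' @param n_boot number of bootstrap resamples.
#' @param level interval coverage.
#' @param seed integer seed.
#' @return named vector `c(lo, hi)`; zero-width with a warning when every
#'   resample gives the same value.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000,
                         level = 0.95, seed = 1) {
  if (length(values) < 2) stop_invalid("need at least 2 values")
  stats_b <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    statistic(sample(values, replace = TRUE)), 1.0))
  if (max(stats_b) == min(stats_b))
    warning("degenerate bootstrap distribution; zero-width interval")
  a <- (1 - level) / 2
  q <- quantile(stats_b, c(a, 1 - a), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Scaled accuracy differences
#'
#' Per-entry `(reference - other) / reference` with entries whose reference
#' magnitude falls below `eps` dropped with a warning; used for the
#' subject-vs-group loss and the within-vs-across (matched vs mismatched)
#' contrasts.
#'
#' @param reference,other equal-length numeric vectors.
#' @param eps minimum |reference| for an entry to be retained.
#' @return list with `values`, `mean`, `sd`, `n_dropped`.
#' @export
scaled_difference <- function(reference, other, eps = 1e-8) {
  if (length(reference) != length(other)) stop_invalid("length mismatch")
  keep <- abs(reference) >= eps
  if (!all(keep)) warning(sum(!keep), " entries with near-zero reference dropped")
  v <- (reference[keep] - other[keep]) / reference[keep]
  list(values = v, mean = mean(v), sd = sd(v), n_dropped = sum(!keep))
}

#' Paired two-sided t statistic
#'
#' Thin wrapper over [stats::t.test()] for contrasting two paired vectors
#' of scaled differences (e.g. the spectral-degradation vs language
#' contrasts).
#'
#' @param x,y equal-length paired numeric vectors.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("length mismatch")
  d <- x - y
  if (sd(d) == 0)
    return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = mean(d)))
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Significance-tier proportions and rank dispersion by condition
#'
#' From a table of per-decoder permutation outcomes, computes for each
#' condition and mode the fraction of decoders in each significance tier
#' and the unscaled MAD of percentile ranks across subjects with its
#' percentile bootstrap confidence interval.
#'
#' @param nulls data.frame with columns `mode`, `subject`, `language`,
#'   `degradation`, `percentile_rank`, `tier`.
#' @param n_boot bootstrap resamples for the MAD interval.
#' @param seed integer seed for the bootstrap.
#' @return data.frame with one row per mode x condition: tier fractions
#'   (`prop_ns`, `prop_05`, `prop_01`, `prop_001`, summing to 1), `n`,
#'   `mad_rank`, `mad_lo`, `mad_hi`.
#' @export
significance_table <- function(nulls, n_boot = 1000, seed = 1) {
  req <- c("mode", "subject", "language", "degradation", "percentile_rank", "tier")
  if (!is.data.frame(nulls) || nrow(nulls) == 0 || !all(req %in% names(nulls)))
    stop_invalid("nulls must be a non-empty data.frame with columns ",
                 paste(req, collapse = ", "))
  groups <- unique(nulls[, c("mode", "language", "degradation")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- nulls$mode == g$mode & nulls$language == g$language &
      nulls$degradation == g$degradation
    ranks <- nulls$percentile_rank[sel]
    tiers <- nulls$tier[sel]
    # a degenerate MAD bootstrap (e.g. every decoder at rank 100) is a
    # legitimate zero-width interval here, not a user error
    ci <- if (length(ranks) >= 2)
      suppressWarnings(bootstrap_ci(ranks, mad_raw, n_boot,
                                    seed = derive_seed(seed, "mad", i)))
    else c(lo = NA_real_, hi = NA_real_)
    data.frame(mode = g$mode, language = g$language,
               degradation = g$degradation, n = sum(sel),
               prop_ns = mean(tiers == "ns"),
               prop_05 = mean(tiers == "p<.05"),
               prop_01 = mean(tiers == "p<.01"),
               prop_001 = mean(tiers == "p<.001"),
               mad_rank = mad_raw(ranks), mad_lo = ci["lo"], mad_hi = ci["hi"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
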