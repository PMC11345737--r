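# End-to-end orchestration: simulate (or load) -> decode -> permutation
# nulls -> report tables, with all randomness derived from one global seed.

#' Run configuration
#'
#' Bundles the decoder, permutation and reporting settings of a pipeline
#' run. `sim` may be omitted when running from files.
#'
#' @param sim a [sim_config()], or `NULL` for file-driven runs.
#' @param modes decoding modes to run, subset of `c("subject", "group")`.
#' @param spec a [lag_spec()].
#' @param k_folds subject-mode cross-validation folds.
#' @param lambda_grid ridge penalty grid.
#' @param n_perm permutations per within-condition subject decoder.
#' @param chunk_s,join_ms segment-shuffle parameters.
#' @param test_window_s evaluation window in seconds.
#' @param seed global seed for permutation streams and bootstraps.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = NULL, modes = c("subject", "group"),
                       spec = lag_spec(), k_folds = 4,
                       lambda_grid = default_lambda_grid(), n_perm = 1000,
                       chunk_s = 3, join_ms = 50, test_window_s = 60,
                       seed = 1) {
  modes <- match.arg(modes, c("subject", "group"), several.ok = TRUE)
  structure(list(sim = sim, modes = modes, spec = spec, k_folds = k_folds,
                 lambda_grid = lambda_grid, n_perm = n_perm,
                 chunk_s = chunk_s, join_ms = join_ms,
                 test_window_s = test_window_s, seed = as.integer(seed)),
            class = "run_config")
}

#' Within-subject concordance between decoding modes
#'
#' Kendall's W between the subject-specific and group-level accuracy
#' rankings of the matched (trained = test condition) results, per subject.
#'
#' @param results generalization results for both modes
#'   (from [generalization_matrix()]).
#' @return data.frame with columns subject, W.
#' @export
concordance_by_subject <- function(results) {
  matched <- results[results$trained_language == results$test_language &
                       results$trained_degradation == results$test_degradation, ]
  subjects <- sort(unique(matched$subject))
  rows <- lapply(subjects, function(s) {
    sub <- matched[matched$subject == s & matched$mode == "subject", ]
    grp <- matched[matched$subject == s & matched$mode == "group", ]
    if (nrow(sub) < 2 || nrow(grp) != nrow(sub)) return(NULL)
    key <- paste(sub$trained_language, sub$trained_degradation)
    grp <- grp[match(key, paste(grp$trained_language, grp$trained_degradation)), ]
    data.frame(subject = s, W = kendalls_w(rbind(sub$r, grp$r)))
  })
  do.call(rbind, rows)
}

#' Matched vs mismatched accuracy summaries
#'
#' Per subject and mode: mean matched (diagonal) accuracy, mean accuracy
#' when only the degradation is mismatched, and when only the language is
#' mismatched.
#'
#' @param results generalization results.
#' @return data.frame with columns mode, subject, matched, mismatch_degradation,
#'   mismatch_language.
#' @export
matched_mismatched <- function(results) {
  out <- list()
  for (md in unique(results$mode)) {
    for (s in sort(unique(results$subject))) {
      d <- results[results$mode == md & results$subject == s, ]
      same_lang <- d$trained_language == d$test_language
      same_deg <- d$trained_degradation == d$test_degradation
      out[[length(out) + 1L]] <- data.frame(
        mode = md, subject = s,
        matched = mean(d$r[same_lang & same_deg]),
        mismatch_degradation = mean(d$r[same_lang & !same_deg]),
        mismatch_language = mean(d$r[!same_lang & same_deg]))
    }
  }
  do.call(rbind, out)
}

# Permutation nulls for the matched subject-specific decoders of a cohort.
cohort_nulls <- function(cohort, results, config) {
  rows <- list()
  for (s in seq_along(cohort$cells)) {
    for (cid in names(cohort$cells[[s]])) {
      cell <- cohort$cells[[s]][[cid]]
      sel <- results$mode == "subject" & results$subject == s &
        results$trained_language == cell$condition$language &
        results$trained_degradation == cell$condition$degradation &
        results$test_language == cell$condition$language &
        results$test_degradation == cell$condition$degradation
      lam <- results$lambda[sel][1]
      nd <- null_distribution(
        cell$train_env, cell$train_eeg, cell$test_env, cell$test_eeg,
        lambda = lam, spec_lag = config$spec,
        spec_shuffle = shuffle_spec(config$chunk_s, config$join_ms,
                                    derive_seed(config$seed, "null", s, cid)),
        n_perm = config$n_perm, test_window_s = config$test_window_s)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = "subject", subject = s,
        language = cell$condition$language,
        degradation = cell$condition$degradation,
        observed_r = nd$observed_r, percentile_rank = nd$percentile_rank,
        tier = nd$tier, n_perm = nd$n_perm, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

analyze_cohort <- function(cohort, config, out_dir) {
  dir.create(file.path(out_dir, "report"), recursive = TRUE, showWarnings = FALSE)
  results <- do.call(rbind, lapply(config$modes, function(md)
    generalization_matrix(cohort, md, config$spec, config$k_folds,
                          config$lambda_grid, config$test_window_s)))
  write_tsv <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(results, file.path(out_dir, "results.tsv"))
  nulls <- cohort_nulls(cohort, results, config)
  write_tsv(nulls, file.path(out_dir, "nulls.tsv"))
  tiers <- significance_table(nulls, seed = derive_seed(config$seed, "tiers"))
  write_tsv(tiers, file.path(out_dir, "report", "tier_proportions.tsv"))
  mm <- matched_mismatched(results)
  write_tsv(mm, file.path(out_dir, "report", "matched_mismatched.tsv"))
  report <- list(results = results, nulls = nulls, tiers = tiers,
                 matched_mismatched = mm)
  if (all(c("subject", "group") %in% config$modes)) {
    conc <- concordance_by_subject(results)
    write_tsv(conc, file.path(out_dir, "report", "concordance.tsv"))
    sub_m <- mm[mm$mode == "subject", ]
    grp_m <- mm[mm$mode == "group", ]
    grp_m <- grp_m[match(sub_m$subject, grp_m$subject), ]
    loss <- scaled_difference(sub_m$matched, grp_m$matched)
    sd_df <- data.frame(subject = sub_m$subject[abs(sub_m$matched) >= 1e-8],
                        scaled_loss = loss$values)
    write_tsv(sd_df, file.path(out_dir, "report", "group_scaled_loss.tsv"))
    report$concordance <- conc
    report$group_scaled_loss <- loss
  }
  manifest <- list(package = "envtrack",
                   version = as.character(utils::packageVersion("envtrack")),
                   seed = config$seed, modes = config$modes,
                   n_perm = config$n_perm, chunk_s = config$chunk_s,
                   lambda_grid = config$lambda_grid,
                   lags_ms = c(config$spec$tmin_ms, config$spec$tmax_ms),
                   k_folds = config$k_folds,
                   sim = if (!is.null(config$sim)) unclass(config$sim))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Run the full simulation study
#'
#' Generates a synthetic cohort from `config$sim`, computes the train x test
#' generalization matrices for the requested modes, builds within-condition
#' permutation nulls for the subject-specific decoders, and writes result
#' and report tables plus a machine-readable run manifest to `out_dir`.
#' Fully deterministic given the configuration.
#'
#' @param config a [run_config()] with a [sim_config()] in `$sim`.
#' @param out_dir output directory.
#' @return invisibly, a list with all computed tables.
#' @export
run_simulation_study <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$sim)) stop_invalid("config$sim required for simulation runs")
  cohort <- make_cohort(config$sim, keep_audio = FALSE)
  analyze_cohort(cohort, config, out_dir)
}

#' Run the pipeline on user-supplied files
#'
#' Reads a cohort from a manifest TSV (columns subject, language,
#' degradation, train_wav, test_wav, train_eeg, test_eeg; paths relative to
#' the manifest), extracts envelopes from the stimulus WAVs, and runs the
#' same decoding, permutation and reporting stages as
#' [run_simulation_study()]. Ground-truth-dependent outputs are unavailable
#' for file cohorts.
#'
#' @param manifest path to the manifest TSV.
#' @param config a [run_config()]; `config$sim` supplies the segment
#'   durations and envelope-extraction settings (defaults are used when
#'   `NULL`).
#' @param out_dir output directory.
#' @return invisibly, a list with all computed tables.
#' @export
run_from_files <- function(manifest, config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(manifest)) stop_invalid("manifest not found: ", manifest)
  df <- utils::read.table(manifest, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_invalid("empty manifest")
  need <- c("subject", "language", "degradation", "train_wav", "test_wav",
            "train_eeg", "test_eeg")
  if (!all(need %in% names(df)))
    stop_invalid("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(manifest)
  for (i in seq_len(nrow(df))) {
    for (col in c("train_wav", "test_wav", "train_eeg", "test_eeg")) {
      p <- file.path(base, df[[col]][i])
      if (!file.exists(p))
        stop_invalid("manifest row ", i, ": missing file ", df[[col]][i])
    }
  }
  sim <- config$sim %||% sim_config(n_subjects = length(unique(df$subject)))
  ep <- sim$env_params
  subjects <- sort(unique(df$subject))
  cells <- lapply(subjects, function(s) {
    sub <- df[df$subject == s, ]
    cell_list <- lapply(seq_len(nrow(sub)), function(i) {
      cond <- condition_label(sub$language[i], sub$degradation[i])
      side <- function(wav_col, eeg_col) {
        env <- extract_envelope(read_wav(file.path(base, sub[[wav_col]][i])),
                                n_filters = ep$n_filters, f_lo = ep$f_lo,
                                f_hi = ep$f_hi,
                                power_exponent = ep$power_exponent,
                                out_rate = sim$env_rate)
        eeg <- read_eeg(file.path(base, sub[[eeg_col]][i]))
        n <- min(length(env$samples), ncol(eeg$data))
        list(env = env_signal(env$samples[seq_len(n)], sim$env_rate),
             eeg = eeg_recording(eeg$data[, seq_len(n), drop = FALSE],
                                 eeg$rate, eeg$channel_labels))
      }
      tr <- side("train_wav", "train_eeg")
      te <- side("test_wav", "test_eeg")
      list(condition = cond,
           train_env = tr$env, test_env = te$env,
           train_eeg = tr$eeg, test_eeg = te$eeg)
    })
    names(cell_list) <- vapply(seq_len(nrow(sub)), function(i)
      paste(sub$language[i], sub$degradation[i], sep = ":"), "")
    cell_list
  })
  cohort <- structure(list(config = sim, conditions = all_conditions(),
                           cells = cells),
                      class = "synthetic_cohort")
  analyze_cohort(cohort, config, out_dir)
}
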