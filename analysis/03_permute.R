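#!/usr/bin/env Rscript
# Stage 3: segment-shuffle permutation nulls for every within-condition
# subject decoder, at the decoder's cross-validated penalty. Writes the
# per-decoder percentile ranks and significance tiers.

source(file.path("analysis", "config.R"))
cfg <- study_run_config()

results <- read.table(file.path(RESULTS_DIR, "results.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
cohort <- make_cohort(cfg$sim, keep_audio = FALSE)
message("Building ", cfg$n_perm, "-permutation nulls for ",
        cfg$sim$n_subjects * 6, " decoders")
nulls <- envtrack:::cohort_nulls(cohort, results, cfg)
write.table(nulls, file.path(RESULTS_DIR, "nulls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d/%d decoders significant at p < .05",
                sum(nulls$tier != "ns"), nrow(nulls)))
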