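#!/usr/bin/env Rscript
# Preprocess the simulated session: sliding-baseline dF/F0, neuropil and
# discriminability QC, per-trial response extraction (with fast-lick
# exclusion and miss-duration matching), z-scoring and preferred-orientation
# assignment. Writes trial_responses.tsv (long format), qc_report.tsv and
# tuning.tsv; caches the dF/F matrix for the later drivers.

library(hetpop)

session <- read_session("results/session")
cfg <- analysis_config(rng_seed = 1L)

dff <- compute_dff(session$soma, session$frame_rate, cfg$baseline_window_s)
saveRDS(dff, "results/cache_dff.rds")

qc <- discriminability_qc(session$soma, session$neuropil, session$frame_rate)
np <- neuropil_correct(session$soma, session$neuropil)
qc$neuropil_r <- attr(np, "r")
write.table(qc, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("QC: ", sum(qc$flagged), " of ", nrow(qc),
    " neurons flagged for discriminability; neuropil r in [",
    round(min(qc$neuropil_r), 2), ", ", round(max(qc$neuropil_r), 2),
    "]\n", sep = "")

responses <- extract_trial_responses(session, dff, cfg)
saveRDS(responses, "results/cache_responses.rds")
long <- data.frame(
  neuron = rep(seq_len(nrow(responses$values)), ncol(responses$values)),
  trial_index = rep(responses$trials$trial_index,
                    each = nrow(responses$values)),
  response = as.numeric(responses$values))
write.table(long, "results/trial_responses.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(nrow(responses$excluded), "trial(s) excluded:",
    paste(unique(responses$excluded$reason), collapse = ", "), "\n")

tuning <- assign_preferred_orientation(responses)
write.table(tuning, "results/tuning.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sum(tuning$consistent), "of", nrow(tuning),
    "neurons consistently tuned; preference counts:\n")
print(table(tuning$preferred_orientation[tuning$consistent]))

z <- zscore_responses(responses, "global")
saveRDS(z, "results/cache_zscores.rds")
cat("z-scored", nrow(z$values), "neurons over", ncol(z$values), "trials\n")
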