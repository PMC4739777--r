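#!/usr/bin/env Rscript
# Naive-Bayes decoding analyses: stimulus presence from the preferred
# population (with behaviour-similarity and chi-square correspondence),
# orientation decoding per contrast with metric-split dependence, 21-way
# stimulus-type decoding for hits vs misses, and single-trial predictive
# decoding of the upcoming response type from pre-stimulus metrics.
# Writes decoding_summary.json.

library(hetpop)

responses <- readRDS("results/cache_responses.rds")
metrics <- readRDS("results/cache_metrics.rds")
cfg <- analysis_config(rng_seed = 1L)
tr <- responses$trials
tuning <- assign_preferred_orientation(responses)

presence <- decode_stimulus_presence(responses, tuning)
cons <- task_contrasts()
beh_rate <- vapply(cons, function(ct) {
  mean(tr$outcome[tr$contrast_pct == ct] %in% c("hit", "false_alarm"))
}, numeric(1))
dec_rate <- vapply(cons, function(ct) {
  ix <- !is.na(presence$trials$decoded_present) &
    presence$trials$contrast_pct == ct
  mean(presence$trials$decoded_present[ix])
}, numeric(1))
sim <- presence_behavior_similarity(dec_rate, beh_rate, iterations = 1000L,
                                    rng_seed = cfg$rng_seed)
chi <- presence_outcome_chisq(presence$trials$decoded_present, tr$outcome)
cat("Decoded-present rate by contrast:",
    paste(sprintf("%g%%: %.2f", cons, dec_rate), collapse = ", "), "\n")
cat(sprintf("Decoder/behaviour similarity r = %.3f (shuffled %.3f)\n",
            sim$similarity, sim$shuffled_similarity))
cat(sprintf("Decoder/outcome chi-square = %.2f (p = %.2g)\n",
            chi$chisq, chi$p_value))

ori <- lapply(setdiff(cons, 0), function(ct) decode_orientation(responses, ct))
names(ori) <- setdiff(cons, 0)
ori <- Filter(Negate(is.null), ori)
acc <- vapply(ori, `[[`, numeric(1), "accuracy")
cat("Orientation decoding accuracy by contrast:",
    paste(sprintf("%s%%: %.2f", names(acc), acc), collapse = ", "), "\n")

correct <- rep(NA, nrow(tr)); ctr <- rep(NA_real_, nrow(tr))
for (o in ori) {
  correct[o$trial_ix] <- o$correct
  ctr[o$trial_ix] <- tr$contrast_pct[o$trial_ix]
}
sp_dff <- decoding_vs_metric_split(correct, metrics$mean_dff, ctr)
sp_het <- decoding_vs_metric_split(correct, metrics$heterogeneity, ctr)
cat(sprintf("Accuracy increase, high vs low half: dF/F %.1f%%, heterogeneity %.1f%%\n",
            sp_dff$percent_increase, sp_het$percent_increase))

st <- decode_stimulus_type(responses)
cat(sprintf("21-way stimulus-type accuracy: hits %.3f, misses %.3f (%d classes)\n",
            st$accuracy_hit, st$accuracy_miss, st$n_classes))

lab <- split_fast_slow(responses)
pred_het <- predictive_decode_response_type(metrics$prestim_heterogeneity, lab)
pred_dff <- predictive_decode_response_type(metrics$prestim_mean_dff, lab)
cat(sprintf("Predictive decoding index: heterogeneity %.3f, mean dF/F %.3f\n",
            pred_het$mean_index, pred_dff$mean_index))

jsonlite::write_json(list(
  presence = list(decoder_rate = dec_rate, behavior_rate = beh_rate,
                  similarity = sim, chisq = chi$chisq,
                  chisq_p = chi$p_value),
  orientation_accuracy = as.list(acc),
  metric_split = list(mean_dff = sp_dff$percent_increase,
                      heterogeneity = sp_het$percent_increase),
  stimulus_type = list(hit = st$accuracy_hit, miss = st$accuracy_miss,
                       n_classes = st$n_classes),
  predictive_index = list(heterogeneity = pred_het$mean_index,
                          mean_dff = pred_dff$mean_index)),
  "results/decoding_summary.json", auto_unbox = TRUE, digits = NA)
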