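#!/usr/bin/env Rscript
# Detection statistics: hit/miss effect sizes and ROC separability for
# heterogeneity vs mean dF/F0, heterogeneity-vs-reaction-time regression,
# 10-90% rise times, pre-stimulus predictability (delta), inter-trial
# pattern consistency vs shuffle, noise correlations for fast vs slow
# trials, and the behavioural Clopper-Pearson detection check. Writes
# detection_stats.json and consistency.tsv.

library(hetpop)

responses <- readRDS("results/cache_responses.rds")
z <- readRDS("results/cache_zscores.rds")
dff <- readRDS("results/cache_dff.rds")
metrics <- readRDS("results/cache_metrics.rds")
cfg <- analysis_config(rng_seed = 1L)
tr <- responses$trials

d_het <- effect_size_by_contrast(metrics$heterogeneity, responses)
d_dff <- effect_size_by_contrast(metrics$mean_dff, responses)
auc_het <- roc_by_contrast(metrics$heterogeneity, responses)
auc_dff <- roc_by_contrast(metrics$mean_dff, responses)
cat(sprintf("Mean hit/miss Cohen's d: heterogeneity %.3f, mean dF/F %.3f\n",
            attr(d_het, "mean_d"), attr(d_dff, "mean_d")))
cat(sprintf("Mean hit/miss ROC AUC:   heterogeneity %.3f, mean dF/F %.3f\n",
            attr(auc_het, "mean_auc"), attr(auc_dff, "mean_auc")))

rt_het <- regress_metric_on_rt(metrics$heterogeneity, responses)
rt_dff <- regress_metric_on_rt(metrics$mean_dff, responses)
cat(sprintf("Heterogeneity ~ RT: slope %.3f (R2 %.3f, p %.2g, n %d)\n",
            rt_het$slope, rt_het$r_squared, rt_het$p_value, rt_het$n))

# rise time of the trial-averaged heterogeneity trace per response type
lab <- split_fast_slow(responses)
tc <- metric_timecourse(dff, responses, z, "heterogeneity",
                        cfg$prestim_window_s)
onset <- attr(tc, "onset_index")
rise <- sapply(c("miss", "slow", "fast"), function(tt) {
  trace <- colMeans(tc[which(lab == tt), , drop = FALSE], na.rm = TRUE)
  rise_time_10_90(trace, onset, responses$frame_rate)
})
cat("10-90% heterogeneity rise times (s):",
    paste(sprintf("%s %.2f", names(rise), rise), collapse = ", "), "\n")

# pre-stimulus predictability per metric and response-type pair
pm <- metrics[, c("prestim_mean_dff", "prestim_heterogeneity")]
blocks <- sort(unique(tr$block_index))
pts <- function(col, tt) sapply(blocks, function(b) {
  ix <- which(lab == tt & tr$block_index == b)
  if (!length(ix)) NA else mean(pm[[col]][ix])
})
pairs <- list(c("fast", "miss"), c("slow", "miss"), c("fast", "slow"))
delta_tab <- do.call(rbind, lapply(names(pm), function(col) {
  do.call(rbind, lapply(pairs, function(pr) {
    a <- pts(col, pr[1]); b <- pts(col, pr[2])
    ok <- stats::complete.cases(a, b)
    data.frame(metric = col, pair = paste(pr, collapse = "_vs_"),
               mean_delta = predictability_delta(a[ok], b[ok])$mean_delta)
  }))
}))
cat("Pre-stimulus predictability delta (per-block points):\n")
print(delta_tab, row.names = FALSE)

tuning <- assign_preferred_orientation(responses)
cons <- pattern_consistency(responses, tuning, lab, iterations = 100L,
                            rng_seed = cfg$rng_seed)
write.table(cons, "results/consistency.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Pattern consistency (preferred population), real vs shuffled:\n")
print(cons[cons$population == "preferred",
           c("response_type", "consistency", "shuffled")], row.names = FALSE)

nc_fast <- noise_correlations(responses, subset = which(lab == "fast"))
nc_slow <- noise_correlations(responses, subset = which(lab == "slow"))
cat(sprintf("Mean noise correlation: fast %.3f, slow %.3f\n",
            mean(nc_fast, na.rm = TRUE), mean(nc_slow, na.rm = TRUE)))

n0 <- sum(tr$contrast_pct == 0)
k0 <- sum(tr$contrast_pct == 0 & tr$outcome == "false_alarm")
n100 <- sum(tr$contrast_pct == 100)
k100 <- sum(tr$contrast_pct == 100 & tr$outcome == "hit")
ci0 <- clopper_pearson_ci(k0, n0)
ci100 <- clopper_pearson_ci(k100, n100)
cat(sprintf("Response rate 95%% CI: 0%% probe [%.2f, %.2f], 100%% [%.2f, %.2f] -> %s\n",
            ci0["lower"], ci0["upper"], ci100["lower"], ci100["upper"],
            if (ci0["upper"] < ci100["lower"]) "significant detection"
            else "not significant"))

jsonlite::write_json(list(
  cohens_d = list(heterogeneity = attr(d_het, "mean_d"),
                  mean_dff = attr(d_dff, "mean_d")),
  roc_auc = list(heterogeneity = attr(auc_het, "mean_auc"),
                 mean_dff = attr(auc_dff, "mean_auc")),
  rt_regression = list(heterogeneity = rt_het, mean_dff = rt_dff),
  rise_time_s = as.list(rise),
  predictability = delta_tab,
  noise_correlation = list(fast = mean(nc_fast, na.rm = TRUE),
                           slow = mean(nc_slow, na.rm = TRUE)),
  behavior_ci = list(probe = as.list(ci0), contrast100 = as.list(ci100))),
  "results/detection_stats.json", auto_unbox = TRUE, digits = NA)
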