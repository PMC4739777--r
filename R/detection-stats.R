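#' Cohen's d with pooled SD
#'
#' Effect size `d = (mean(a) - mean(b)) / s_pooled`, where the pooled SD is
#' `sqrt(((n_a - 1) var_a + (n_b - 1) var_b) / (n_a + n_b - 2))`.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return Scalar effect size.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2))
  if (sp == 0) stop("pooled SD is zero")
  (mean(group_a) - mean(group_b)) / sp
}

#' Per-contrast hit/miss effect sizes for a metric
#'
#' @param metric Per-trial metric values aligned with `responses$trials`.
#' @param responses A `hetpop_responses` object.
#' @param contrasts Contrasts to evaluate (default test contrasts).
#' @return Data frame of `contrast_pct`, `d`, plus `mean_d` attribute (mean
#'   over contrasts with >= 2 trials per group).
#' @export
effect_size_by_contrast <- function(metric, responses,
                                    contrasts = test_contrasts()) {
  tr <- responses$trials
  d <- vapply(contrasts, function(ct) {
    h <- metric[tr$contrast_pct == ct & tr$outcome == "hit"]
    m <- metric[tr$contrast_pct == ct & tr$outcome == "miss"]
    if (length(h) < 2 || length(m) < 2) return(NA_real_)
    cohens_d(h, m)
  }, numeric(1))
  out <- data.frame(contrast_pct = contrasts, d = d)
  attr(out, "mean_d") <- mean(d, na.rm = TRUE)
  out
}

#' ROC area under the curve via the rank statistic
#'
#' AUC of hit-vs-miss separation for a per-trial metric, computed as the
#' normalised Mann-Whitney U statistic with mid-ranks (ties count half) —
#' exactly the area under the empirical TPR-vs-FPR curve.
#'
#' @param hit_values,miss_values Numeric vectors (both nonempty).
#' @return AUC in `[0, 1]`; 0.5 is chance.
#' @export
roc_auc <- function(hit_values, miss_values) {
  stopifnot(length(hit_values) > 0, length(miss_values) > 0)
  r <- rank(c(hit_values, miss_values))
  nh <- length(hit_values); nm <- length(miss_values)
  (sum(r[seq_len(nh)]) - nh * (nh + 1) / 2) / (nh * nm)
}

#' Per-contrast hit/miss ROC AUC for a metric
#'
#' @inheritParams effect_size_by_contrast
#' @return Data frame of `contrast_pct`, `auc`; attribute `mean_auc`.
#' @export
roc_by_contrast <- function(metric, responses, contrasts = test_contrasts()) {
  tr <- responses$trials
  auc <- vapply(contrasts, function(ct) {
    h <- metric[tr$contrast_pct == ct & tr$outcome == "hit"]
    m <- metric[tr$contrast_pct == ct & tr$outcome == "miss"]
    if (length(h) == 0 || length(m) == 0) return(NA_real_)
    roc_auc(h, m)
  }, numeric(1))
  out <- data.frame(contrast_pct = contrasts, auc = auc)
  attr(out, "mean_auc") <- mean(auc, na.rm = TRUE)
  out
}

#' Ordinary least-squares regression of a metric on reaction time
#'
#' Fits `metric ~ reaction_time` over hit trials of one session. Group-level
#' inference (across sessions/animals) is a one-sample t-test of the
#' per-session slopes against zero with Bonferroni-Holm correction; see
#' [holm_slope_test()].
#'
#' @param metric Per-trial metric values aligned with `responses$trials`.
#' @param responses A `hetpop_responses` object.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress_metric_on_rt <- function(metric, responses) {
  tr <- responses$trials
  ix <- which(tr$outcome == "hit" & is.finite(tr$reaction_time_s))
  stopifnot(length(ix) >= 3)
  rt <- tr$reaction_time_s[ix]
  if (sd(rt) == 0) stop("degenerate reaction-time variance")
  fit <- lm(metric[ix] ~ rt)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4], n = length(ix))
}

#' Holm-corrected one-sample t-tests of regression slopes
#'
#' @param slopes Numeric vector (one slope per session) or a list of such
#'   vectors for several metrics.
#' @return Data frame with t statistic, raw and Holm-adjusted p per entry.
#' @export
holm_slope_test <- function(slopes) {
  if (!is.list(slopes)) slopes <- list(slope = slopes)
  tests <- lapply(slopes, function(s) t.test(s, mu = 0))
  p <- vapply(tests, function(t) t$p.value, numeric(1))
  data.frame(metric = names(slopes),
             t = vapply(tests, function(t) unname(t$statistic), numeric(1)),
             p = p, p_holm = p.adjust(p, method = "holm"))
}

#' 10-90% rise time of a metric trace
#'
#' Baseline is the mean over the pre-stimulus window; the maximum is taken
#' over the post-onset part of the trace. The 10% and 90% levels of the
#' baseline-to-maximum excursion are located by linear interpolation at
#' their first post-onset crossings; the rise time is the time between
#' them. Undefined (NA, with a warning) when the maximum does not exceed
#' baseline.
#'
#' @param trace Numeric per-frame metric trace (may contain trailing NAs).
#' @param onset_index 1-based index of the stimulus-onset frame.
#' @param frame_rate Frames per second.
#' @return Rise time in seconds, or NA if undefined.
#' @export
rise_time_10_90 <- function(trace, onset_index, frame_rate) {
  stopifnot(onset_index >= 2, onset_index <= length(trace))
  base <- mean(trace[seq_len(onset_index - 1)], na.rm = TRUE)
  post <- trace[onset_index:length(trace)]
  post <- post[!is.na(post)]
  if (length(post) < 2) return(NA_real_)
  mx <- max(post)
  if (mx <= base) {
    warning("trace maximum does not exceed baseline; rise time undefined")
    return(NA_real_)
  }
  cross_time <- function(level) {
    above <- which(post >= level)
    if (length(above) == 0) return(NA_real_)
    k <- above[1]
    if (k == 1) return(0)
    frac <- (level - post[k - 1]) / (post[k] - post[k - 1])
    (k - 2 + frac) / frame_rate
  }
  t10 <- cross_time(base + 0.1 * (mx - base))
  t90 <- cross_time(base + 0.9 * (mx - base))
  t90 - t10
}

#' Split hit trials into fastest and slowest halves per contrast
#'
#' Labels each trial `miss`, `fast` or `slow` (probe trials get NA). Within
#' each contrast the `floor(n/2)` fastest hits are `fast` and the rest
#' `slow`, so with odd counts the median trial goes to `slow`; a contrast
#' with a single hit labels it `slow`.
#'
#' @param responses A `hetpop_responses` object.
#' @return Character vector of response-type labels aligned with
#'   `responses$trials`.
#' @export
split_fast_slow <- function(responses) {
  tr <- responses$trials
  lab <- rep(NA_character_, nrow(tr))
  lab[tr$outcome == "miss"] <- "miss"
  for (ct in unique(tr$contrast_pct[tr$outcome == "hit"])) {
    ix <- which(tr$outcome == "hit" & tr$contrast_pct == ct)
    n_fast <- floor(length(ix) / 2)
    ord <- ix[order(tr$reaction_time_s[ix])]
    lab[ord] <- "slow"
    if (n_fast > 0) lab[ord[seq_len(n_fast)]] <- "fast"
  }
  lab
}

#' Leave-one-out predictability of response type from pre-stimulus points
#'
#' For two response types r1 and r2, each r1 point i is scored by its
#' distance to the r2 group mean versus its own group's leave-one-out mean:
#' `delta = 2 * (d(i, mu_r2) / (d(i, mu_r2) + d(i, mu_r1_without_i)) - 0.5)`.
#' `delta = +1` when the point sits on its own group mean, `-1` when it sits
#' on the other group's mean, and 0 in expectation for randomly placed
#' points. If both distances are zero, `delta = 0` by convention.
#'
#' @param points_r1 Matrix (rows = points) or vector of the r1 group.
#' @param points_r2 Matrix or vector of the r2 group.
#' @return List: `delta` (per r1 point), `mean_delta`.
#' @export
predictability_delta <- function(points_r1, points_r2) {
  p1 <- if (is.matrix(points_r1)) points_r1 else matrix(points_r1, ncol = 1)
  p2 <- if (is.matrix(points_r2)) points_r2 else matrix(points_r2, ncol = 1)
  stopifnot(nrow(p1) >= 2, nrow(p2) >= 1)
  mu2 <- colMeans(p2)
  delta <- vapply(seq_len(nrow(p1)), function(i) {
    mu1_loo <- colMeans(p1[-i, , drop = FALSE])
    d_other <- sqrt(sum((p1[i, ] - mu2)^2))
    d_own <- sqrt(sum((p1[i, ] - mu1_loo)^2))
    if (d_other + d_own == 0) return(0)
    2 * (d_other / (d_other + d_own) - 0.5)
  }, numeric(1))
  list(delta = delta, mean_delta = mean(delta))
}

#' Inter-trial population activation pattern consistency
#'
#' For each stimulus orientation (test contrasts pooled) and response type
#' (miss/slow/fast), computes the mean Pearson correlation between the
#' response vectors of all same-type trial pairs, separately for the
#' population preferring that orientation and the nonpreferred population.
#' The chance level is estimated by shuffling, within each orientation,
#' every neuron's trial identities independently (which preserves the
#' orientation signal but destroys trial-specific co-activation), repeated
#' `iterations` times and averaged.
#'
#' @param responses A `hetpop_responses` object.
#' @param tuning Output of [assign_preferred_orientation()].
#' @param response_type Per-trial labels from [split_fast_slow()].
#' @param iterations Shuffle iterations (default 100).
#' @param contrasts Contrasts pooled (default test contrasts).
#' @param rng_seed Seed for the shuffle.
#' @return Data frame: `response_type`, `population`
#'   (preferred/nonpreferred), `consistency`, `shuffled`, `n_pairs`.
#' @export
pattern_consistency <- function(responses, tuning, response_type,
                                iterations = 100L,
                                contrasts = test_contrasts(), rng_seed = 1L) {
  tr <- responses$trials
  values <- responses$values
  use <- which(tr$contrast_pct %in% contrasts & !is.na(response_type))
  oris <- task_orientations()
  types <- c("miss", "slow", "fast")

  mean_pair_cor <- function(mat) {
    # mean over unique column-pair Pearson correlations
    if (ncol(mat) < 2) return(c(cor = NA_real_, n = 0))
    cm <- suppressWarnings(cor(mat))
    v <- cm[upper.tri(cm)]
    c(cor = mean(v, na.rm = TRUE), n = sum(!is.na(v)))
  }

  cell_values <- function(vals) {
    out <- expand.grid(response_type = types,
                       population = c("preferred", "nonpreferred"),
                       stringsAsFactors = FALSE)
    out$consistency <- NA_real_; out$n_pairs <- 0
    for (r in seq_len(nrow(out))) {
      per_ori <- vapply(oris, function(o) {
        ix <- use[tr$orientation_deg[use] == o &
                    response_type[use] == out$response_type[r]]
        if (length(ix) < 2) return(c(NA_real_, 0))
        pop <- if (out$population[r] == "preferred") {
          which(tuning$consistent & tuning$preferred_orientation == o)
        } else {
          which(tuning$consistent & tuning$preferred_orientation != o)
        }
        if (length(pop) < 2) return(c(NA_real_, 0))
        mean_pair_cor(vals[pop, ix, drop = FALSE])
      }, numeric(2))
      out$consistency[r] <- mean(per_ori[1, ], na.rm = TRUE)
      out$n_pairs[r] <- sum(per_ori[2, ])
    }
    out
  }

  real <- cell_values(values)

  rs <- local_rng(rng_seed, 303L)
  on.exit(restore_rng(rs))
  shuf_acc <- matrix(0, nrow(real), iterations)
  for (it in seq_len(iterations)) {
    vals_s <- values
    for (o in oris) {
      ix <- use[tr$orientation_deg[use] == o]
      if (length(ix) < 2) next
      for (i in seq_len(nrow(values))) {
        vals_s[i, ix] <- values[i, ix[sample.int(length(ix))]]
      }
    }
    shuf_acc[, it] <- cell_values(vals_s)$consistency
  }
  real$shuffled <- rowMeans(shuf_acc, na.rm = TRUE)
  real
}

#' Noise correlations averaged over orientations
#'
#' For each neuron pair and stimulus orientation, the Pearson correlation
#' of the two neurons' responses over repeated presentations (test
#' contrasts, within the given trial subset) is computed; the noise
#' correlation is the mean over the four orientations. Orientations with
#' fewer than `min_reps` repetitions, or with zero-variance response
#' vectors for a pair, are excluded from that pair's average.
#'
#' @param responses A `hetpop_responses` object.
#' @param subset Logical or integer index of trials to use (default: all
#'   test-contrast trials).
#' @param min_reps Minimum repetitions per orientation.
#' @return Symmetric matrix `[n x n]` of noise correlations (NA diagonal),
#'   with attribute `n_orientations_used` per pair.
#' @export
noise_correlations <- function(responses, subset = NULL, min_reps = 3L) {
  tr <- responses$trials
  values <- responses$values
  if (is.null(subset)) subset <- tr$contrast_pct %in% test_contrasts()
  ix_all <- seq_len(nrow(tr))[subset]
  n <- nrow(values)
  acc <- matrix(0, n, n); cnt <- matrix(0L, n, n)
  for (o in task_orientations()) {
    ix <- ix_all[tr$orientation_deg[ix_all] == o &
                   tr$contrast_pct[ix_all] %in% test_contrasts()]
    if (length(ix) < min_reps) next
    cm <- suppressWarnings(cor(t(values[, ix, drop = FALSE])))
    ok <- is.finite(cm)
    acc[ok] <- acc[ok] + cm[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  out <- acc / cnt
  out[cnt == 0] <- NA
  diag(out) <- NA
  attr(out, "n_orientations_used") <- cnt
  out
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The 2.5th-97.5th percentile exact interval for a response proportion.
#' "Significant detection" in the task is defined as non-overlap of the
#' 0%-probe and 100%-contrast intervals.
#'
#' @param successes,trials Counts, `0 <= successes <= trials`, `trials > 0`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
clopper_pearson_ci <- function(successes, trials, level = 0.95) {
  stopifnot(trials > 0, successes >= 0, successes <= trials)
  ci <- binom.test(successes, trials, conf.level = level)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction of a p-value vector.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values (monotone in the ranks of the input).
#' @export
fdr_correct <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH")
}
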