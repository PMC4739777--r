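# Gaussian naive-Bayes machinery shared by all decoders. All likelihoods
# are evaluated in log space; class priors are uniform (maximum-likelihood
# read-out); SDs are floored at 1e-6 to guard degenerate variances.

SIGMA_FLOOR <- 1e-6

gnb_loglik <- function(x, mu, sigma) {
  sigma <- pmax(sigma, SIGMA_FLOOR)
  sum(dnorm(x, mu, sigma, log = TRUE))
}

#' Leave-one-out Gaussian naive-Bayes decoder
#'
#' Generic engine: per held-out trial, class-conditional per-feature means
#' are estimated from all remaining trials and the class with the highest
#' summed log likelihood is decoded (ties break toward the first class
#' level, deterministically). Classes with fewer than 2 training trials
#' after holdout make the trial undecodable (NA).
#'
#' With `pooled_sd = FALSE` each class also gets its own per-feature SD.
#' With `pooled_sd = TRUE` a single within-class SD per feature (pooled
#' over classes, still excluding the held-out trial) is used. Per-class
#' SDs keep the decoder sensitive to class differences in response
#' variability (the default, matching the mean-and-SD likelihood model
#' used throughout); note that with very few trials per class they bias
#' leave-one-out accuracy *below* chance under shuffled labels, because
#' the held-out trial is excluded from its own class's variance estimate
#' and extreme trials are then penalised in their true class. At the
#' task's native repetition counts (>= 10-15 trials per class) the bias
#' is negligible; the pooled estimator avoids it entirely at the cost of
#' variance sensitivity.
#'
#' @param features Matrix `[n_features x n_trials]`.
#' @param labels Class label per trial (factor or character).
#' @param pooled_sd Use one within-class SD per feature (see Details).
#' @return List: `decoded` (label per trial), `posterior` (matrix of
#'   normalised relative likelihoods, trials x classes), `correct`.
#' @export
loo_gaussian_nb <- function(features, labels, pooled_sd = FALSE) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  labels <- as.character(labels)
  classes <- unique(labels)
  n_tr <- ncol(features)
  stopifnot(length(labels) == n_tr)
  post <- matrix(NA_real_, n_tr, length(classes),
                 dimnames = list(NULL, classes))
  decoded <- rep(NA_character_, n_tr)
  for (t in seq_len(n_tr)) {
    mus <- lapply(classes, function(cl) {
      ix <- setdiff(which(labels == cl), t)
      if (length(ix) < 2) return(NULL)
      list(ix = ix, mu = rowMeans(features[, ix, drop = FALSE]))
    })
    names(mus) <- classes
    if (any(vapply(mus, is.null, logical(1)))) next
    if (pooled_sd) {
      # within-class SD pooled over classes, excluding the held-out trial
      ss <- 0; df <- 0
      for (m in mus) {
        dev <- features[, m$ix, drop = FALSE] - m$mu
        ss <- ss + rowSums(dev^2)
        df <- df + length(m$ix) - 1
      }
      sg_pool <- sqrt(ss / df)
    }
    ll <- vapply(classes, function(cl) {
      m <- mus[[cl]]
      sg <- if (pooled_sd) sg_pool
            else apply(features[, m$ix, drop = FALSE], 1, sd)
      gnb_loglik(features[, t], m$mu, sg)
    }, numeric(1))
    rel <- exp(ll - max(ll))
    post[t, ] <- rel / sum(rel)
    decoded[t] <- classes[which.max(ll)]
  }
  list(decoded = decoded, posterior = post, correct = decoded == labels)
}

#' Decode stimulus presence from the preferred population
#'
#' A two-class maximum-likelihood decoder replicating the animal's task:
#' for each trial, the summed log Gaussian likelihood of the preferred
#' population's responses (neurons whose preferred orientation matches the
#' trial's stimulus orientation) is evaluated under a "stimulus absent"
#' model fitted on 0%-probe trials and a "stimulus present" model fitted on
#' same-orientation 100%-contrast trials; the larger likelihood is the
#' read-out (ties break toward "absent"). Test contrasts are automatically
#' cross-validated (they never enter the models); 0% and 100% trials are
#' decoded leave-one-out. Trials whose preferred population is empty are
#' skipped with a log entry.
#'
#' @param responses A `hetpop_responses` object.
#' @param tuning Output of [assign_preferred_orientation()].
#' @return List: `trials` (per-trial data frame with `decoded_present`),
#'   `present_rate` (contrast x response-type table of decoded-present
#'   proportions), `skipped` (trial indices without preferred neurons).
#' @export
decode_stimulus_presence <- function(responses, tuning) {
  tr <- responses$trials
  values <- responses$values
  absent_ix <- which(tr$contrast_pct == 0)
  stopifnot(length(absent_ix) >= 2)
  decoded <- rep(NA, nrow(tr))
  skipped <- integer(0)
  for (t in seq_len(nrow(tr))) {
    o <- tr$orientation_deg[t]
    pop <- which(tuning$consistent & tuning$preferred_orientation == o)
    if (length(pop) == 0) { skipped <- c(skipped, t); next }
    a_ix <- setdiff(absent_ix, t)
    p_ix <- setdiff(which(tr$contrast_pct == 100 & tr$orientation_deg == o), t)
    if (length(a_ix) < 2 || length(p_ix) < 2) { skipped <- c(skipped, t); next }
    mu_a <- rowMeans(values[pop, a_ix, drop = FALSE])
    sd_a <- apply(values[pop, a_ix, drop = FALSE], 1, sd)
    mu_p <- rowMeans(values[pop, p_ix, drop = FALSE])
    sd_p <- apply(values[pop, p_ix, drop = FALSE], 1, sd)
    ll_a <- gnb_loglik(values[pop, t], mu_a, sd_a)
    ll_p <- gnb_loglik(values[pop, t], mu_p, sd_p)
    decoded[t] <- ll_p > ll_a  # tie -> absent
  }
  out <- data.frame(trial_index = tr$trial_index,
                    contrast_pct = tr$contrast_pct,
                    outcome = tr$outcome,
                    decoded_present = decoded)
  rate <- aggregate(decoded_present ~ contrast_pct + outcome,
                    data = out[!is.na(out$decoded_present), ], FUN = mean)
  list(trials = out, present_rate = rate, skipped = skipped)
}

#' Similarity of decoder and behavioural psychometric curves
#'
#' Pearson correlation, over contrast levels, between the decoder's
#' decoded-present rate and the animal's behavioural response rate. The
#' chance level is the mean correlation after independently shuffling the
#' contrast labels of both curves (default 1000 iterations).
#'
#' @param decoder_rate,behavior_rate Numeric vectors over the same
#'   contrasts (>= 3 levels).
#' @param iterations Shuffle iterations.
#' @param rng_seed Seed for the shuffle.
#' @return List: `similarity`, `shuffled_similarity`.
#' @export
presence_behavior_similarity <- function(decoder_rate, behavior_rate,
                                         iterations = 1000L, rng_seed = 1L) {
  stopifnot(length(decoder_rate) == length(behavior_rate),
            length(decoder_rate) >= 3)
  if (sd(decoder_rate) == 0 || sd(behavior_rate) == 0) {
    stop("zero variance in a performance curve")
  }
  sim <- cor(decoder_rate, behavior_rate)
  rs <- local_rng(rng_seed, 404L)
  on.exit(restore_rng(rs))
  k <- length(decoder_rate)
  shuf <- vapply(seq_len(iterations), function(i) {
    suppressWarnings(cor(decoder_rate[sample.int(k)],
                         behavior_rate[sample.int(k)]))
  }, numeric(1))
  list(similarity = sim, shuffled_similarity = mean(shuf, na.rm = TRUE))
}

#' Chi-square correspondence between decoder and behaviour
#'
#' Pearson chi-square (no continuity correction) on the pooled 2x2 table of
#' decoded presence against behavioural outcome (hit/miss).
#'
#' @param decoded_present Logical per trial.
#' @param outcome Character per trial (`hit`/`miss`).
#' @return List: `chisq`, `p_value`, `table`.
#' @export
presence_outcome_chisq <- function(decoded_present, outcome) {
  keep <- !is.na(decoded_present) & outcome %in% c("hit", "miss")
  tab <- table(decoded = decoded_present[keep], outcome = outcome[keep])
  if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square needs a 2x2 table with all margins > 0")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), p_value = ct$p.value, table = tab)
}

#' Leave-one-out orientation decoding per contrast
#'
#' Four-class Gaussian naive Bayes on all neurons' responses, fitted and
#' evaluated within one contrast. Contrasts where any orientation has
#' fewer than 2 trials are skipped.
#'
#' @param responses A `hetpop_responses` object.
#' @param contrast Single contrast (percent) to decode within.
#' @return List: `accuracy`, `decoded`, `correct`, `trial_ix` (indices into
#'   `responses$trials`), or NULL if the contrast is skipped.
#' @export
decode_orientation <- function(responses, contrast) {
  tr <- responses$trials
  ix <- which(tr$contrast_pct == contrast)
  labs <- as.character(tr$orientation_deg[ix])
  if (length(ix) == 0 || any(table(labs) < 2) ||
      length(unique(labs)) < 2) {
    return(NULL)
  }
  fit <- loo_gaussian_nb(responses$values[, ix, drop = FALSE], labs)
  list(accuracy = mean(fit$correct, na.rm = TRUE), decoded = fit$decoded,
       correct = fit$correct, trial_ix = ix)
}

#' Decoding-accuracy dependence on a population metric
#'
#' Splits each contrast's trials into the highest and lowest 50% of a
#' per-trial metric (odd counts put the median trial in the low half) and
#' contrasts mean decoding accuracy between the halves, expressed as the
#' percentage accuracy increase of the high over the low half, averaged
#' over contrasts. Contrasts with a zero low-half accuracy are flagged and
#' excluded from the percentage average.
#'
#' @param correct Logical per trial (decoder correctness).
#' @param metric Per-trial metric values.
#' @param contrasts Per-trial contrast labels.
#' @return List: `percent_increase` (mean over contrasts), `per_contrast`
#'   (data frame), `flagged` (contrasts with zero low-half accuracy).
#' @export
decoding_vs_metric_split <- function(correct, metric, contrasts) {
  stopifnot(length(correct) == length(metric),
            length(metric) == length(contrasts))
  rows <- lapply(unique(contrasts), function(ct) {
    ix <- which(contrasts == ct & !is.na(correct))
    if (length(ix) < 4) return(NULL)
    ord <- ix[order(metric[ix])]
    n_hi <- floor(length(ix) / 2)
    hi <- tail(ord, n_hi); lo <- head(ord, length(ix) - n_hi)
    data.frame(contrast_pct = ct, acc_high = mean(correct[hi]),
               acc_low = mean(correct[lo]))
  })
  per <- do.call(rbind, rows)
  if (is.null(per)) stop("no contrast with >= 4 decodable trials")
  per$percent_increase <- ifelse(per$acc_low > 0,
                                 100 * (per$acc_high - per$acc_low) / per$acc_low,
                                 NA_real_)
  list(percent_increase = mean(per$percent_increase, na.rm = TRUE),
       per_contrast = per,
       flagged = per$contrast_pct[is.na(per$percent_increase)])
}

#' Leave-one-out 21-class stimulus-type decoding
#'
#' Classes are the 4 orientations x 5 nonzero contrasts plus the pooled
#' 0%-probe class (21 total). Classes with fewer than 2 trials are dropped
#' (with a message) and the class set renormalised. Accuracy is averaged
#' per class within hit and miss trials separately, then over classes.
#'
#' @param responses A `hetpop_responses` object.
#' @return List: `accuracy_hit`, `accuracy_miss`, `n_classes`, `decoded`,
#'   `correct`.
#' @export
decode_stimulus_type <- function(responses) {
  tr <- responses$trials
  labs <- ifelse(tr$contrast_pct == 0, "probe",
                 paste0(tr$orientation_deg, "@", tr$contrast_pct))
  counts <- table(labs)
  keep_classes <- names(counts)[counts >= 2]
  if (length(keep_classes) < length(counts)) {
    message("dropping under-sampled stimulus class(es): ",
            paste(setdiff(names(counts), keep_classes), collapse = ", "))
  }
  ix <- which(labs %in% keep_classes)
  fit <- loo_gaussian_nb(responses$values[, ix, drop = FALSE], labs[ix])
  per_class_acc <- function(outcome) {
    accs <- vapply(keep_classes, function(cl) {
      sel <- labs[ix] == cl & tr$outcome[ix] == outcome
      if (!any(sel)) return(NA_real_)
      mean(fit$correct[sel], na.rm = TRUE)
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }
  list(accuracy_hit = per_class_acc("hit"),
       accuracy_miss = per_class_acc("miss"),
       n_classes = length(keep_classes),
       decoded = fit$decoded, correct = fit$correct, trial_ix = ix)
}

#' Single-trial predictive decoding of the upcoming response type
#'
#' Decodes, from a scalar pre-stimulus metric (heterogeneity or mean
#' dF/F0), the relative likelihood that the upcoming stimulus leads to a
#' miss, slow or fast response (leave-one-out Gaussian naive Bayes). Per
#' true response type, the three relative likelihoods are averaged and
#' mapped onto the unit circle (classes at 0, 2pi/3, 4pi/3); the resultant
#' vector's alignment with the true class angle times its magnitude gives
#' a normalised decoding accuracy index in `[-1, +1]` with chance at 0.
#'
#' @param prestim_values Numeric per-trial pre-stimulus metric.
#' @param labels Per-trial response type (`miss`/`slow`/`fast`; NA ignored).
#' @return List: `per_type` (data frame with resultant angle, magnitude and
#'   `index` per true type), `mean_index`, `likelihoods` (type x type mean
#'   relative likelihoods).
#' @export
predictive_decode_response_type <- function(prestim_values, labels) {
  types <- c("miss", "slow", "fast")
  keep <- which(labels %in% types)
  stopifnot(length(keep) > 0)
  x <- prestim_values[keep]; lab <- labels[keep]
  stopifnot(all(table(factor(lab, levels = types)) >= 2))
  fit <- loo_gaussian_nb(matrix(x, nrow = 1), lab)
  post <- fit$posterior[, types, drop = FALSE]
  angles <- setNames(c(0, 2 * pi / 3, 4 * pi / 3), types)
  lik <- t(vapply(types, function(tt) {
    colMeans(post[lab == tt, , drop = FALSE], na.rm = TRUE)
  }, numeric(3)))
  dimnames(lik) <- list(true = types, decoded = types)
  per <- lapply(types, function(tt) {
    p <- lik[tt, ]
    vx <- sum(p * cos(angles)); vy <- sum(p * sin(angles))
    mag <- sqrt(vx^2 + vy^2)
    # index = cos(angle difference to the true class) * magnitude,
    # i.e. the resultant's projection onto the true-class direction
    idx <- vx * cos(angles[tt]) + vy * sin(angles[tt])
    data.frame(response_type = tt, angle = atan2(vy, vx), magnitude = mag,
               index = idx)
  })
  per <- do.call(rbind, per)
  list(per_type = per, mean_index = mean(per$index), likelihoods = lik)
}
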