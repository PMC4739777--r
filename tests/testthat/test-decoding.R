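test_that("LOO naive Bayes matches a Gaussian density oracle", {
  # single neuron, classes N(0,1) vs N(2,1), observation 1.5: the density
  # under the 'present' class (0.3521) beats 'absent' (0.1295)
  expect_gt(dnorm(1.5, 2, 1), dnorm(1.5, 0, 1))
  # engine-level check on a 3-neuron, 12-trial instance vs brute force
  set.seed(1)
  feats <- matrix(rnorm(36), 3, 12)
  labs <- rep(c("a", "b"), each = 6)
  feats[, labs == "b"] <- feats[, labs == "b"] + 1
  fit <- loo_gaussian_nb(feats, labs)
  for (t in 1:12) {
    ll <- sapply(c("a", "b"), function(cl) {
      ix <- setdiff(which(labs == cl), t)
      sum(dnorm(feats[, t], rowMeans(feats[, ix]),
                pmax(apply(feats[, ix], 1, sd), 1e-6), log = TRUE))
    })
    expect_equal(fit$decoded[t], names(which.max(ll)))
    expect_equal(fit$posterior[t, "a"],
                 exp(ll["a"]) / sum(exp(ll - max(ll)) * exp(max(ll))),
                 tolerance = 1e-9)
  }
})

test_that("LOO partitioning never trains on the held-out trial", {
  # mutation audit: make one trial a wild outlier; if it leaked into its
  # own training stats, its class SD would explode and flip the decision
  feats <- matrix(c(rep(0, 5), 100, rep(5, 6)), 1, 12)
  labs <- rep(c("a", "b"), each = 6)
  fit <- loo_gaussian_nb(feats, labs)
  # trial 6 (the outlier, true 'a') must be decoded from stats of
  # trials 1-5 (mean 0) vs 7-12 (mean 5): closer to b in likelihood
  expect_equal(fit$decoded[6], "b")
  # remaining 'a' trials decode correctly (outlier inflates 'a' SD but
  # they sit exactly on the 'a' mean)
  expect_true(all(fit$correct[1:5]))
})

test_that("presence decoder reads out the preferred population", {
  p <- small_pipeline(seed = 3, n_blocks = 3)
  tuning <- assign_preferred_orientation(p$responses)
  out <- decode_stimulus_presence(p$responses, tuning)
  tr <- out$trials
  ok <- !is.na(tr$decoded_present)
  # 100% contrast trials should mostly decode present; probes mostly absent
  expect_gt(mean(tr$decoded_present[ok & tr$contrast_pct == 100]), 0.7)
  expect_lt(mean(tr$decoded_present[ok & tr$contrast_pct == 0]), 0.3)
  # decoded-present rate grows with contrast
  rate <- sapply(c(0, 0.5, 2, 8, 32, 100), function(ct)
    mean(tr$decoded_present[ok & tr$contrast_pct == ct]))
  expect_gt(cor(rate, seq_along(rate), method = "spearman"), 0.7)
})

test_that("behaviour similarity is 1/-1 for identical/anti-monotone curves and ~0 shuffled", {
  curve <- c(0.1, 0.2, 0.4, 0.6, 0.8, 0.9)
  out <- presence_behavior_similarity(curve, curve, iterations = 500)
  expect_equal(out$similarity, 1)
  expect_lt(abs(out$shuffled_similarity), 0.1)
  out2 <- presence_behavior_similarity(curve, rev(curve), iterations = 10)
  expect_equal(out2$similarity, -1)
  expect_error(presence_behavior_similarity(rep(0.5, 6), curve),
               "zero variance")
})

test_that("chi-square correspondence matches the closed form", {
  # table [[30,10],[10,30]] -> chisq = n(ad-bc)^2 / (r1 r2 c1 c2) = 20
  dec <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 30))
  outc <- c(rep("hit", 40), rep("miss", 40))
  out <- presence_outcome_chisq(dec, outc)
  expect_equal(out$chisq, 20, tolerance = 1e-12)
  # perfectly concordant table -> chisq = n
  dec2 <- c(rep(TRUE, 20), rep(FALSE, 20))
  outc2 <- c(rep("hit", 20), rep("miss", 20))
  expect_equal(presence_outcome_chisq(dec2, outc2)$chisq, 40,
               tolerance = 1e-12)
  # empty margin -> error
  expect_error(presence_outcome_chisq(rep(TRUE, 10), rep("hit", 10)))
  # independence: statistic ~ df = 1 on average
  set.seed(2)
  stats <- replicate(300, {
    presence_outcome_chisq(sample(c(TRUE, FALSE), 80, TRUE),
                           sample(c("hit", "miss"), 80, TRUE))$chisq
  })
  expect_equal(mean(stats), 1, tolerance = 0.25)
})

test_that("orientation decoding is perfect on separable responses and skips thin classes", {
  oris <- rep(c(0, 45, 90, 135), each = 4)
  n_tr <- length(oris)
  tr <- data.frame(trial_index = seq_len(n_tr) - 1L, direction_deg = oris,
                   contrast_pct = 100, onset_frame = seq_len(n_tr) * 100,
                   offset_frame = seq_len(n_tr) * 100 + 50,
                   outcome = "hit", reaction_time_s = 1, block_index = 1L,
                   orientation_deg = oris,
                   analysis_offset_frame = seq_len(n_tr) * 100 + 50)
  set.seed(3)
  values <- sapply(oris, function(o) {
    as.numeric(o == c(0, 45, 90, 135)) + rnorm(4, sd = 0.01)
  })
  rsp <- structure(list(values = values, trials = tr, frame_rate = 25.4),
                   class = "hetpop_responses")
  out <- decode_orientation(rsp, 100)
  expect_equal(out$accuracy, 1.0)
  # a contrast with a 1-trial class is skipped
  tr2 <- tr[-(1:3), ]
  rsp2 <- structure(list(values = values[, -(1:3)], trials = tr2,
                         frame_rate = 25.4), class = "hetpop_responses")
  expect_null(decode_orientation(rsp2, 100))
})

test_that("metric split reproduces a hand-computed 8-trial fixture", {
  correct <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  metric <- c(8, 7, 6, 5, 4, 3, 2, 1)
  contrasts <- rep(8, 8)
  out <- decoding_vs_metric_split(correct, metric, contrasts)
  # high half = metric {8,7,6,5}: acc 0.75; low half {4,3,2,1}: acc 0.25
  expect_equal(out$per_contrast$acc_high, 0.75)
  expect_equal(out$per_contrast$acc_low, 0.25)
  expect_equal(out$percent_increase, 200)
  # metric independent of correctness -> increase near 0 over Monte-Carlo
  set.seed(4)
  incs <- replicate(300, {
    decoding_vs_metric_split(sample(c(TRUE, FALSE), 40, TRUE, prob = c(0.7, 0.3)),
                             rnorm(40), rep(8, 40))$percent_increase
  })
  expect_lt(abs(mean(incs)), 8)
  # zero low-half accuracy flagged
  out2 <- decoding_vs_metric_split(c(FALSE, FALSE, TRUE, TRUE),
                                   c(1, 2, 3, 4), rep(8, 4))
  expect_equal(out2$flagged, 8)
})

test_that("stimulus-type decoding uses 21 classes and is near-perfect when separable", {
  p <- small_pipeline(seed = 3, n_blocks = 3)
  # class bookkeeping: 4 orientations x 5 nonzero contrasts + probe = 21
  tr <- p$responses$trials
  labs <- ifelse(tr$contrast_pct == 0, "probe",
                 paste0(tr$orientation_deg, "@", tr$contrast_pct))
  expect_equal(length(unique(labs)), 21)
  out <- decode_stimulus_type(p$responses)
  expect_lte(out$n_classes, 21)

  # separable classes (one indicator neuron per class, tiny noise)
  classes <- unique(labs)
  set.seed(5)
  values <- sapply(labs, function(l) {
    as.numeric(l == classes) * 2 + rnorm(21, sd = 0.01)
  })
  rsp <- structure(list(values = values, trials = tr, frame_rate = 25.4),
                   class = "hetpop_responses")
  out2 <- decode_stimulus_type(rsp)
  expect_gt(mean(out2$correct, na.rm = TRUE), 0.95)
})

test_that("angular predictive index hits its anchors", {
  # all likelihood on the true class -> +1; on a wrong class -> -0.5;
  # uniform likelihoods -> 0
  lab <- rep(c("miss", "slow", "fast"), each = 10)
  # construct separable pre-stimulus values
  x <- rep(c(0, 5, 10), each = 10) + rnorm(30, sd = 0.1)
  set.seed(6)
  out <- predictive_decode_response_type(x, lab)
  expect_gt(out$mean_index, 0.9)
  # wrong-class anchor via angular arithmetic
  expect_equal(cos(2 * pi / 3) * 1, -0.5)
  # chance anchor: equal likelihoods give zero resultant
  p <- c(1, 1, 1) / 3
  angles <- c(0, 2 * pi / 3, 4 * pi / 3)
  expect_equal(sqrt(sum(p * cos(angles))^2 + sum(p * sin(angles))^2), 0,
               tolerance = 1e-12)
})

test_that("decoders sit at chance under label shuffling", {
  # engine-level calibration at the task's native class sizes (>= 15
  # trials per class, where the per-class-SD leave-one-out estimator is
  # unbiased): shuffled 4-class labels decode at 25%
  set.seed(7)
  accs <- replicate(30, {
    feats <- matrix(rnorm(30 * 80), 30, 80)
    labs <- sample(rep(c("0", "45", "90", "135"), each = 20))
    mean(loo_gaussian_nb(feats, labs)$correct, na.rm = TRUE)
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.25), 3 * se + 0.01)

  # and 2-class shuffled labels decode at 50%
  accs2 <- replicate(30, {
    feats <- matrix(rnorm(30 * 60), 30, 60)
    labs <- sample(rep(c("hit", "miss"), each = 30))
    mean(loo_gaussian_nb(feats, labs)$correct, na.rm = TRUE)
  })
  se2 <- sd(accs2) / sqrt(length(accs2))
  expect_lt(abs(mean(accs2) - 0.5), 3 * se2 + 0.01)
})
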