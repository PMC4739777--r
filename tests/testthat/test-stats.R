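test_that("Cohen's d matches the pooled-SD hand oracle", {
  # mean difference 1, both variances 1, equal n -> d = 1
  a <- c(0, 1, 2); b <- c(1, 2, 3)
  expect_equal(cohens_d(b, a), 1)
  expect_equal(cohens_d(a, a), 0)
  # groups {0,2} vs {1,3}: mu diff -1, pooled SD sqrt(2) -> -1/sqrt(2)
  expect_equal(cohens_d(c(0, 2), c(1, 3)), -1 / sqrt(2), tolerance = 1e-12)
  # sign flips when groups swap; invariant to common shifts
  set.seed(1)
  x <- rnorm(10); y <- rnorm(12, 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_equal(cohens_d(x + 7, y + 7), cohens_d(x, y), tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled SD")
})

test_that("rank AUC equals the brute-force all-pairs win fraction", {
  expect_equal(roc_auc(c(3, 4, 5), c(0, 1, 2)), 1.0)
  expect_equal(roc_auc(c(1, 3), 2), 0.5)  # one win, one loss
  set.seed(2)
  for (i in 1:5) {
    h <- rnorm(sample(5:100, 1))
    m <- rnorm(sample(5:100, 1), 0.3)
    expect_equal(roc_auc(h, m), oracle_auc(h, m), tolerance = 1e-12)
  }
  # ties count half
  expect_equal(roc_auc(c(1, 1), c(1, 1)), 0.5)
  # identical distributions -> near 0.5 over Monte-Carlo
  set.seed(3)
  aucs <- replicate(200, roc_auc(rnorm(40), rnorm(40)))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("rank AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(4)
  h <- rnorm(30, 0.5); m <- rnorm(25)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 30), rep(0, 25)), predictor = c(h, m),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(h, m), ref, tolerance = 1e-12)
})

test_that("metric-on-RT regression recovers exact linear relations", {
  tr <- data.frame(trial_index = 0:9, direction_deg = 0, contrast_pct = 8,
                   onset_frame = 0:9 * 100, offset_frame = 0:9 * 100 + 50,
                   outcome = "hit",
                   reaction_time_s = seq(0.2, 2.0, length.out = 10),
                   block_index = 1L, orientation_deg = 0,
                   analysis_offset_frame = 0:9 * 100 + 50)
  rsp <- structure(list(values = matrix(0, 2, 10), trials = tr,
                        frame_rate = 25.4), class = "hetpop_responses")
  fit <- suppressWarnings(regress_metric_on_rt(2 * tr$reaction_time_s, rsp))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # metric independent of RT -> slope near 0 over Monte-Carlo
  set.seed(5)
  slopes <- replicate(200, regress_metric_on_rt(rnorm(10), rsp)$slope)
  expect_lt(abs(mean(slopes)), 0.2)

  # Holm-corrected group test over per-session slopes
  res <- holm_slope_test(list(het = c(-1, -2, -1.5, -0.8),
                              dff = c(0.1, -0.2, 0.05, 0.02)))
  expect_equal(res$p_holm, p.adjust(res$p, "holm"))
  expect_lt(res$p[res$metric == "het"], 0.05)
})

test_that("10-90% rise time matches analytic crossing times", {
  fr <- 100
  # linear ramp 0 -> 1 over 1 s from onset, baseline 0: crossings at
  # 0.1 s and 0.9 s -> rise time 0.8 s
  trace <- c(rep(0, 100), seq(0, 1, length.out = 101), rep(1, 50))
  expect_equal(rise_time_10_90(trace, 101, fr), 0.8, tolerance = 1e-2)
  # instantaneous step -> within one frame's interpolation of 0
  step <- c(rep(0, 100), rep(1, 100))
  expect_lt(rise_time_10_90(step, 101, fr), 1 / fr)
  # flat trace -> undefined, flagged
  expect_warning(out <- rise_time_10_90(rep(1, 200), 101, fr),
                 "undefined")
  expect_true(is.na(out))
})

test_that("fast/slow split follows the per-contrast median rule", {
  tr <- data.frame(trial_index = 0:5, direction_deg = 0,
                   contrast_pct = c(8, 8, 8, 8, 8, 32),
                   onset_frame = 0:5 * 100, offset_frame = 0:5 * 100 + 50,
                   outcome = c("hit", "hit", "hit", "miss", "hit", "hit"),
                   reaction_time_s = c(1, 2, 3, NA, 0.5, 1.2),
                   block_index = 1L, orientation_deg = 0,
                   analysis_offset_frame = 0:5 * 100 + 50)
  rsp <- structure(list(values = matrix(0, 2, 6), trials = tr,
                        frame_rate = 25.4), class = "hetpop_responses")
  lab <- split_fast_slow(rsp)
  # contrast 8 hits have RTs {1, 2, 3, 0.5}: two fastest (0.5, 1) -> fast
  expect_equal(lab[tr$contrast_pct == 8 & tr$outcome == "hit"],
               c("fast", "slow", "slow", "fast"))
  expect_equal(lab[4], "miss")
  # single hit at contrast 32 -> slow
  expect_equal(lab[6], "slow")

  # odd counts put the median in slow: RTs {1,2,3} -> fast, slow, slow
  tr2 <- tr[1:3, ]
  rsp2 <- structure(list(values = matrix(0, 2, 3), trials = tr2,
                         frame_rate = 25.4), class = "hetpop_responses")
  expect_equal(split_fast_slow(rsp2), c("fast", "slow", "slow"))
})

test_that("predictability delta hits its degenerate anchors", {
  # point at its own leave-one-out mean, other mean distinct -> +1
  p1 <- rbind(c(1, 1), c(1, 1), c(1, 1))
  p2 <- rbind(c(5, 5), c(6, 6))
  expect_equal(predictability_delta(p1, p2)$delta, rep(1, 3))
  # point at the other group's mean -> -1
  p1 <- rbind(c(5.5, 5.5), c(0, 0), c(1, 1))
  d <- predictability_delta(p1, p2)$delta
  expect_equal(d[1], -1)
  # both distances zero -> 0 by convention
  p_same <- rbind(c(2, 2), c(2, 2), c(2, 2))
  expect_equal(predictability_delta(p_same, p_same)$delta, rep(0, 3))
})

test_that("delta is near zero for a common distribution (null)", {
  set.seed(6)
  deltas <- replicate(500, {
    pool <- matrix(rnorm(32), 16, 2)
    mean(c(predictability_delta(pool[1:8, ], pool[9:16, ])$delta,
           predictability_delta(pool[9:16, ], pool[1:8, ])$delta))
  })
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 0.02)
})

test_that("pattern consistency finds identical vectors and audits shuffles", {
  # the two fast trials carry identical response vectors -> their pair
  # correlation is exactly 1
  set.seed(7)
  v <- rnorm(10)
  tr <- data.frame(trial_index = 0:5, direction_deg = 0, contrast_pct = 8,
                   onset_frame = 0:5 * 100, offset_frame = 0:5 * 100 + 50,
                   outcome = c("hit", "hit", "hit", "hit", "miss", "miss"),
                   reaction_time_s = c(0.5, 0.6, 1.5, 1.6, NA, NA),
                   block_index = 1L, orientation_deg = 0,
                   analysis_offset_frame = 0:5 * 100 + 50)
  values <- cbind(v, v, rnorm(10), rnorm(10), rnorm(10), rnorm(10))
  rsp <- structure(list(values = values, trials = tr, frame_rate = 25.4),
                   class = "hetpop_responses")
  tuning <- data.frame(neuron = 1:10,
                       preferred_orientation = rep(c(0, 90), 5),
                       consistent = TRUE)
  lab <- split_fast_slow(rsp)
  expect_equal(lab, c("fast", "fast", "slow", "slow", "miss", "miss"))
  out <- pattern_consistency(rsp, tuning, lab, iterations = 10)
  pref_fast <- out$consistency[out$response_type == "fast" &
                                 out$population == "preferred"]
  expect_equal(pref_fast, 1, tolerance = 1e-12)
})

test_that("pattern consistency is at chance for iid responses", {
  set.seed(8)
  p <- small_pipeline(seed = 30, n_blocks = 2, n_neurons = 30)
  tr <- p$responses$trials
  iid <- matrix(rnorm(length(p$responses$values)),
                nrow(p$responses$values))
  rsp <- structure(list(values = iid, trials = tr, frame_rate = 25.4),
                   class = "hetpop_responses")
  tuning <- data.frame(neuron = seq_len(nrow(iid)),
                       preferred_orientation = rep(task_orientations(),
                                                   length.out = nrow(iid)),
                       consistent = TRUE)
  lab <- split_fast_slow(rsp)
  out <- pattern_consistency(rsp, tuning, lab, iterations = 30)
  ok <- !is.na(out$consistency)
  expect_lt(max(abs(out$consistency[ok] - out$shuffled[ok])), 0.12)
})

test_that("noise correlations average per-orientation correlations", {
  # two neurons with identical repetition vectors -> rho = 1
  tr <- expand.grid(rep = 1:5, direction_deg = c(0, 45, 90, 135))
  n_tr <- nrow(tr)
  tr <- data.frame(trial_index = seq_len(n_tr) - 1L,
                   direction_deg = tr$direction_deg, contrast_pct = 8,
                   onset_frame = seq_len(n_tr) * 100,
                   offset_frame = seq_len(n_tr) * 100 + 50,
                   outcome = "miss", reaction_time_s = NA, block_index = 1L,
                   orientation_deg = fold_direction(tr$direction_deg),
                   analysis_offset_frame = seq_len(n_tr) * 100 + 50)
  set.seed(9)
  base <- rnorm(n_tr)
  values <- rbind(base, base, rnorm(n_tr))
  rsp <- structure(list(values = values, trials = tr, frame_rate = 25.4),
                   class = "hetpop_responses")
  nc <- noise_correlations(rsp)
  expect_equal(nc[1, 2], 1, tolerance = 1e-12)
  expect_true(is.na(nc[1, 1]))
  expect_equal(nc, t(nc))
  expect_equal(attr(nc, "n_orientations_used")[1, 2], 4L)

  # independent neurons -> mean rho near 0 over Monte-Carlo
  set.seed(10)
  rhos <- replicate(100, {
    v <- matrix(rnorm(2 * n_tr), 2, n_tr)
    r2 <- structure(list(values = v, trials = tr, frame_rate = 25.4),
                    class = "hetpop_responses")
    noise_correlations(r2)[1, 2]
  })
  expect_lt(abs(mean(rhos)), 0.1)

  # one orientation degenerate -> averaged over the remaining three
  values2 <- values
  values2[1, tr$orientation_deg == 0] <- 5  # zero variance for neuron 1
  r3 <- structure(list(values = values2, trials = tr, frame_rate = 25.4),
                  class = "hetpop_responses")
  nc3 <- noise_correlations(r3)
  expect_equal(attr(nc3, "n_orientations_used")[1, 2], 3L)
  expect_false(is.na(nc3[1, 2]))
})

test_that("Clopper-Pearson interval matches the closed form", {
  expect_equal(clopper_pearson_ci(0, 10)[["lower"]], 0)
  # 10/10 at 95%: lower bound = 0.025^(1/10)
  expect_equal(clopper_pearson_ci(10, 10)[["lower"]], 0.025^(1 / 10),
               tolerance = 1e-9)
  expect_equal(clopper_pearson_ci(10, 10)[["upper"]], 1)
  expect_error(clopper_pearson_ci(1, 0))
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # monotone in the ranks of the input
  set.seed(11)
  p <- runif(20)
  adj <- fdr_correct(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(fdr_correct(c(0.5, 1.2)))
})
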