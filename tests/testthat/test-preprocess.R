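test_that("sliding-baseline dF/F matches hand and brute-force oracles", {
  # constant trace -> dF/F identically 0
  f <- matrix(100, 2, 50)
  expect_equal(compute_dff(f, 10, 30), matrix(0, 2, 50),
               ignore_attr = TRUE)

  # single spike with window covering the whole trace: baseline stays at
  # 100 (lowest half excludes the spike), spike frame reads 0.5
  f <- matrix(100, 1, 61)
  f[1, 30] <- 150
  d <- compute_dff(f, 1, 200)
  expect_equal(d[1, 30], 0.5)
  expect_equal(d[1, 1], 0)

  # random trace vs O(F*W) per-frame sort oracle, including edge truncation
  set.seed(42)
  f <- matrix(100 + 20 * abs(rnorm(2 * 500)), 2, 500)
  expect_equal(compute_dff(f, 10, 30), oracle_dff(f, 10, 30),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("nonpositive baselines flag the neuron", {
  f <- matrix(c(rep(-5, 50), rep(100, 50)), 2, 50, byrow = TRUE)
  expect_warning(d <- compute_dff(f, 10, 2), "nonpositive baseline")
  expect_equal(attr(d, "flagged_neurons"), 1)
})

test_that("neuropil correction recovers r and cancels shared signal", {
  # neuropil identical to soma -> r = 1, corrected trace identically 0
  x <- matrix(rnorm(200), 2, 100)
  out <- neuropil_correct(x, x)
  expect_equal(attr(out, "r"), c(1, 1))
  expect_equal(out, matrix(0, 2, 100), ignore_attr = TRUE)

  # independent soma and neuropil -> r ~ 0, corrected ~ soma
  set.seed(8)
  soma <- matrix(rnorm(2 * 5000), 2, 5000)
  np <- matrix(rnorm(2 * 5000), 2, 5000)
  out <- neuropil_correct(soma, np)
  expect_lt(max(abs(attr(out, "r"))), 0.05)
  expect_lt(max(abs(out - soma)), 0.2)

  # zero-variance neuropil -> r set to 0 with a warning
  expect_warning(out <- neuropil_correct(soma, matrix(1, 2, 5000)),
                 "zero-variance")
  expect_equal(attr(out, "r"), c(0, 0))
})

test_that("generator neuropil contamination yields r in the plausible range", {
  p <- small_pipeline(seed = 4, n_blocks = 1)
  out <- neuropil_correct(p$session$soma, p$session$neuropil)
  r <- attr(out, "r")
  expect_gt(mean(r > 0.05 & r < 0.75), 0.9)
})

test_that("discriminability QC measures sub-threshold epochs", {
  # equal soma and neuropil -> D_r = 0.5 everywhere, flagged
  f <- matrix(50, 1, 100)
  qc <- discriminability_qc(f, f, 10)
  expect_equal(attr(qc, "dr")[1, 1], 0.5)
  expect_equal(qc$max_epoch_s, 10)
  expect_true(qc$flagged)

  # soma 3x neuropil -> D_r = 0.75, no flags
  qc <- discriminability_qc(3 * f, f, 10)
  expect_equal(attr(qc, "dr")[1, 1], 0.75)
  expect_equal(qc$max_epoch_s, 0)
  expect_false(qc$flagged)

  # 1.0 s boundary: epoch of exactly 10 frames at 10 Hz is not flagged,
  # 11 frames is
  soma <- matrix(100, 1, 100)
  soma[1, 11:20] <- 10
  expect_false(discriminability_qc(soma, matrix(50, 1, 100), 10)$flagged)
  soma[1, 21] <- 10
  expect_true(discriminability_qc(soma, matrix(50, 1, 100), 10)$flagged)
})

test_that("trial extraction excludes fast licks and matches miss durations", {
  fr <- 10
  trials <- data.frame(
    trial_index = 0:4,
    direction_deg = c(0, 0, 0, 90, 0),
    contrast_pct = c(8, 8, 8, 8, 0),
    onset_frame = c(10, 50, 90, 130, 170),
    offset_frame = c(20, 80, 120, 160, 200),
    outcome = c("hit", "miss", "hit", "miss", "correct_rejection"),
    reaction_time_s = c(1.0, NA, 0.1, NA, NA),
    block_index = 1L)
  soma <- matrix(100, 2, 250)
  s <- session_data(fr, soma, trials)
  dff <- matrix(0.2, 2, 250)
  out <- extract_trial_responses(s, dff, analysis_config(rng_seed = 1))

  # constant dF/F -> response 0.2 regardless of duration
  expect_true(all(abs(out$values - 0.2) < 1e-12))
  # RT 0.1 s < 150 ms threshold -> excluded as fast lick
  expect_equal(out$excluded$trial_index, 2)
  expect_equal(as.character(out$excluded$reason), "fast_lick")
  expect_equal(ncol(out$values), 4)
  # single hit RT 1.0 s at contrast 8 -> every miss there gets 1.0 s
  miss_rows <- out$trials$outcome == "miss"
  expect_equal(out$trials$analysis_offset_frame[miss_rows] -
                 out$trials$onset_frame[miss_rows],
               rep(round(1.0 * fr), 2))
  # analysis interval never exceeds the stimulus interval
  expect_true(all(out$trials$analysis_offset_frame <= out$trials$offset_frame))

  # reproducible given the config seed
  out2 <- extract_trial_responses(s, dff, analysis_config(rng_seed = 1))
  expect_identical(out$trials, out2$trials)
  # column order follows trial order (no reordering after exclusion)
  expect_equal(out$trials$trial_index, c(0, 1, 3, 4))
})

test_that("z-scoring matches the sample-SD oracle and drops flat neurons", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5), 2, 3, byrow = TRUE)
  expect_warning(z <- zscore_responses(m), "zero-variance")
  expect_equal(z$values, matrix(c(-1, 0, 1), 1), ignore_attr = TRUE)
  expect_equal(z$kept_neurons, 1)

  # global scope: every retained row has mean 0, sd 1
  set.seed(3)
  m <- matrix(rnorm(40 * 30), 40, 30)
  z <- zscore_responses(m)
  expect_lt(max(abs(rowMeans(z$values))), 1e-10)
  expect_lt(max(abs(apply(z$values, 1, sd) - 1)), 1e-10)
})

test_that("per-contrast z-scoring standardises within each stratum", {
  set.seed(4)
  m <- matrix(rnorm(10 * 24), 10, 24)
  contrasts <- rep(c(0, 8, 100), each = 8)
  z <- zscore_responses(m, "per_contrast", contrasts = contrasts)
  for (ct in unique(contrasts)) {
    sub <- z$values[, contrasts == ct]
    expect_lt(max(abs(rowMeans(sub))), 1e-10)
    expect_lt(max(abs(apply(sub, 1, sd) - 1)), 1e-10)
  }
})

test_that("preferred orientation assignment and consistency filter", {
  # neuron responding only on 90-degree trials prefers 90 and is consistent
  trials <- data.frame(
    trial_index = 0:7,
    direction_deg = rep(c(0, 90, 180, 270), 2),
    contrast_pct = 100,
    onset_frame = seq(0, 70, 10),
    offset_frame = seq(5, 75, 10),
    outcome = "hit", reaction_time_s = 0.5,
    block_index = rep(1:2, each = 4))
  resp <- structure(list(
    values = rbind(c(0, 1, 0, 1, 0, 1, 0, 1),
                   c(1, 0, 1, 0, 1, 0, 1, 0)),
    trials = transform(trials, orientation_deg = fold_direction(direction_deg),
                       analysis_offset_frame = offset_frame),
    frame_rate = 10), class = "hetpop_responses")
  tun <- assign_preferred_orientation(resp)
  expect_equal(tun$preferred_orientation, c(90, 0))
  expect_true(all(tun$consistent))

  # disagreement in exactly 1/3 of blocks stays consistent (boundary)
  bp <- matrix(c(0, 0, 90), 1, 3)
  modal <- 0
  expect_true(mean(bp != modal) <= 1 / 3)
})

test_that("untuned neurons are usually rejected by the consistency filter", {
  # 8 blocks of uniform random per-block preferences: the modal preference
  # rarely captures >= 2/3 of blocks
  set.seed(11)
  frac_consistent <- mean(replicate(1000, {
    p <- sample(c(0, 45, 90, 135), 8, replace = TRUE)
    modal <- names(which.max(table(p)))
    mean(p != as.numeric(modal)) <= 1 / 3
  }))
  expect_lt(frac_consistent, 0.25)
})

test_that("tuned generator neurons are mostly assigned their true orientation", {
  p <- small_pipeline(seed = 2, n_blocks = 2)
  tun <- assign_preferred_orientation(p$responses)
  agree <- mean(tun$preferred_orientation ==
                  p$gen$truth$preferred_orientation)
  expect_gt(agree, 0.8)
})
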