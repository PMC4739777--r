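# Small programmatic fixtures shared across test files.

# A tiny hand-buildable session: n neurons, a few trials, constant frame rate.
tiny_session <- function(n_neurons = 2, n_frames = 100, trials = NULL,
                         frame_rate = 10) {
  soma <- matrix(100 + seq_len(n_neurons * n_frames) %% 7, n_neurons, n_frames)
  if (is.null(trials)) {
    trials <- data.frame(
      trial_index = 0:3,
      direction_deg = c(0, 90, 180, 0),
      contrast_pct = c(100, 8, 100, 0),
      onset_frame = c(10, 30, 50, 70),
      offset_frame = c(20, 40, 60, 80),
      outcome = c("hit", "miss", "hit", "correct_rejection"),
      reaction_time_s = c(1.0, NA, 0.9, NA),
      block_index = 1L)
  }
  session_data(frame_rate, soma, trials)
}

# A small effectful synthetic session plus its preprocessing products.
# Cached per (seed, n_blocks) within one test run.
.small_cache <- new.env(parent = emptyenv())
small_pipeline <- function(seed = 1, n_blocks = 2, ...) {
  key <- paste(seed, n_blocks, ...)
  if (!is.null(.small_cache[[key]])) return(.small_cache[[key]])
  g <- generate_session(synth_config(seed = seed, n_blocks = n_blocks, ...))
  cfg <- analysis_config(rng_seed = seed)
  dff <- compute_dff(g$session$soma, g$session$frame_rate,
                     cfg$baseline_window_s)
  responses <- extract_trial_responses(g$session, dff, cfg)
  z <- zscore_responses(responses, "global")
  out <- list(gen = g, session = g$session, dff = dff,
              responses = responses, z = z, config = cfg)
  .small_cache[[key]] <- out
  out
}

# Brute-force oracles -------------------------------------------------------

# per-frame sort-and-average sliding baseline (O(F * W log W))
oracle_dff <- function(f, frame_rate, window_s = 30) {
  w <- round(window_s * frame_rate)
  h <- floor(w / 2)
  F <- ncol(f)
  out <- f
  for (r in seq_len(nrow(f))) {
    for (i in seq_len(F)) {
      win <- f[r, max(1, i - h):min(F, i + h)]
      k <- max(1, floor(length(win) / 2))
      f0 <- mean(sort(win)[seq_len(k)])
      out[r, i] <- (f[r, i] - f0) / f0
    }
  }
  out
}

# double-loop heterogeneity
oracle_heterogeneity <- function(z) {
  apply(z, 2, function(x) {
    n <- length(x); s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + abs(x[i] - x[j])
    s / (n * (n - 1) / 2)
  })
}

# all-pairs win fraction AUC
oracle_auc <- function(hits, misses) {
  wins <- 0
  for (h in hits) for (m in misses) {
    wins <- wins + (h > m) + 0.5 * (h == m)
  }
  wins / (length(hits) * length(misses))
}
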