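#' Synthetic-session generator configuration
#'
#' Parameters of the generative model used to emulate the go/no-go
#' detection task: 8 drifting-grating directions x 6 contrasts (0, 0.5, 2,
#' 8, 32, 100%) presented once each per randomised 48-trial block, stimulus
#' window up to 3 s, inter-trial interval 10-12 s, orientation-tuned neurons
#' imaged at 25.4 Hz. Neurons are von-Mises tuned in orientation with
#' Naka-Rushton contrast gain; behaviour follows a logistic psychometric
#' function of log contrast; reaction times shorten with contrast and with a
#' latent per-trial arousal state (AR(1)) that also raises pre-stimulus
#' response dispersion. Every neuron carries a spontaneous baseline drive;
#' during a trial each neuron's activity (baseline plus stimulus-evoked) is
#' scaled by a log-normal unit-mean per-trial gain. Hit trials carry (i)
#' per-neuron gains with a larger spread than miss trials, which raises
#' response heterogeneity at every contrast while leaving the expected
#' population mean unchanged, (ii) a small additive population boost, and
#' (iii) a fixed hit-pattern vector making hit activation patterns
#' partially consistent across trials. A per-trial multiplicative gain
#' shared by the whole population emulates global cortical rate
#' fluctuations. Spike-rate-like drive is convolved with a single
#' exponential calcium kernel and observed with additive noise.
#'
#' @param n_neurons Number of neurons (study range 68-130).
#' @param n_blocks Number of 48-trial repetition blocks.
#' @param frame_rate Imaging rate, Hz.
#' @param tuning_concentration Von-Mises concentration on the doubled
#'   orientation angle (unitless).
#' @param contrast_semisaturation Naka-Rushton c50, percent contrast.
#' @param contrast_exponent Naka-Rushton exponent.
#' @param response_amp Peak dF/F drive for a preferred, 100%-contrast
#'   stimulus.
#' @param baseline_drive Spontaneous dF/F-scale drive present throughout
#'   the recording; per-trial gains act on it, so gain-spread differences
#'   raise heterogeneity even at low contrast.
#' @param psychometric_params List: `lapse`, `false_alarm`, `threshold`
#'   (contrast in percent at the 50% point of the detection component) and
#'   `slope` (logistic slope per log2-contrast unit).
#' @param rt_params List: `base` (s), `contrast_speedup` (s, scaled by the
#'   Naka-Rushton contrast drive), `arousal_speedup` (s per arousal SD),
#'   `jitter` (mean of the exponential positive jitter, s).
#' @param hit_gain_spread Log-scale spread of the per-neuron log-normal
#'   unit-mean multiplicative gain on hit trials (must exceed
#'   `miss_gain_spread` for an effectful model).
#' @param miss_gain_spread Gain SD on miss/probe trials.
#' @param common_gain_sd SD of a per-trial multiplicative gain shared by
#'   the whole population, independent of outcome. Emulates the global
#'   rate fluctuations of cortical populations; it makes the population
#'   mean a noisy single-trial readout while leaving relative activation
#'   patterns (and hence heterogeneity) largely untouched.
#' @param hit_mean_boost Additive population dF/F on hits.
#' @param hit_pattern_strength Amplitude of the fixed hit-pattern vector.
#' @param arousal_autocorr AR(1) coefficient of the latent arousal state.
#' @param prestim_sd SD of per-trial per-neuron pre-stimulus activity
#'   offsets (dF/F) at neutral arousal.
#' @param arousal_dispersion_gain Log-scale gain of pre-stimulus dispersion
#'   per arousal SD.
#' @param calcium_tau Indicator decay time constant, s.
#' @param noise_sd Additive fluorescence noise SD (fraction of baseline).
#' @param neuropil_contamination Length-2 range of per-neuron contamination
#'   ratios, within `[0.1, 0.6]`.
#' @param seed Integer RNG seed.
#' @return An object of class `hetpop_synth_config`.
#' @export
synth_config <- function(n_neurons = 80L,
                         n_blocks = 8L,
                         frame_rate = 25.4,
                         tuning_concentration = 1.5,
                         contrast_semisaturation = 8,
                         contrast_exponent = 1.2,
                         response_amp = 0.5,
                         baseline_drive = 0.12,
                         psychometric_params = list(lapse = 0.10,
                                                    false_alarm = 0.15,
                                                    threshold = 2,
                                                    slope = 1.0),
                         rt_params = list(base = 1.6,
                                          contrast_speedup = 0.7,
                                          arousal_speedup = 0.25,
                                          jitter = 0.25),
                         hit_gain_spread = 0.5,
                         miss_gain_spread = 0.15,
                         common_gain_sd = 0.2,
                         hit_mean_boost = 0.002,
                         hit_pattern_strength = 0.25,
                         arousal_autocorr = 0.5,
                         prestim_sd = 0.15,
                         arousal_dispersion_gain = 0.5,
                         calcium_tau = 0.7,
                         noise_sd = 0.03,
                         neuropil_contamination = c(0.1, 0.6),
                         seed = 1L) {
  cfg <- list(n_neurons = as.integer(n_neurons), n_blocks = as.integer(n_blocks),
              frame_rate = frame_rate,
              tuning_concentration = tuning_concentration,
              contrast_semisaturation = contrast_semisaturation,
              contrast_exponent = contrast_exponent,
              response_amp = response_amp,
              baseline_drive = baseline_drive,
              psychometric_params = psychometric_params,
              rt_params = rt_params,
              hit_gain_spread = hit_gain_spread,
              miss_gain_spread = miss_gain_spread,
              common_gain_sd = common_gain_sd,
              hit_mean_boost = hit_mean_boost,
              hit_pattern_strength = hit_pattern_strength,
              arousal_autocorr = arousal_autocorr,
              prestim_sd = prestim_sd,
              arousal_dispersion_gain = arousal_dispersion_gain,
              calcium_tau = calcium_tau,
              noise_sd = noise_sd,
              neuropil_contamination = neuropil_contamination,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_neurons >= 2, n_blocks >= 1, frame_rate > 0,
              hit_gain_spread >= 0, miss_gain_spread >= 0,
              hit_mean_boost >= 0 || TRUE,
              psychometric_params$lapse >= 0, psychometric_params$lapse <= 1,
              psychometric_params$false_alarm >= 0,
              psychometric_params$false_alarm <= 1,
              noise_sd >= 0, prestim_sd >= 0, calcium_tau > 0,
              length(neuropil_contamination) == 2,
              neuropil_contamination[1] >= 0.1,
              neuropil_contamination[2] <= 0.6)
  })
  structure(cfg, class = "hetpop_synth_config")
}

#' Null generator configuration (no hit-related structure)
#'
#' Removes every hit/arousal effect the pipeline is designed to detect:
#' equal gain spread on hits and misses, no mean boost, no hit pattern, and
#' no arousal coupling to reaction time or pre-stimulus dispersion. Used by
#' the calibration suite: all detectors must sit at chance on sessions
#' generated from this configuration.
#'
#' @param seed Integer RNG seed.
#' @param ... Further overrides passed to [synth_config()].
#' @return A `hetpop_synth_config`.
#' @export
synth_config_null <- function(seed = 1L, ...) {
  synth_config(hit_gain_spread = 0.15, miss_gain_spread = 0.15,
               hit_mean_boost = 0, hit_pattern_strength = 0,
               rt_params = list(base = 1.6, contrast_speedup = 0.7,
                                arousal_speedup = 0, jitter = 0.25),
               arousal_dispersion_gain = 0, seed = seed, ...)
}

naka_rushton <- function(contrast, c50, q) {
  ifelse(contrast <= 0, 0, contrast^q / (contrast^q + c50^q))
}

psychometric_p <- function(contrast, pp) {
  ifelse(contrast <= 0, pp$false_alarm,
         pp$false_alarm + (1 - pp$false_alarm - pp$lapse) *
           stats::plogis(pp$slope * (log2(contrast) - log2(pp$threshold))))
}

#' Simulate behavioural outcomes and reaction times
#'
#' Draws one outcome and (for responses) one reaction time per condition.
#' Response probability follows a logistic psychometric function of log2
#' contrast with lapse and false-alarm rates (0% contrast responds at the
#' false-alarm rate). Reaction time is
#' `base - contrast_speedup * NR(c) - arousal_speedup * arousal + jitter`
#' with exponential positive jitter, truncated to `(0, 3]` s.
#'
#' @param conditions Data frame with columns `direction_deg`, `contrast_pct`.
#' @param config A `hetpop_synth_config`.
#' @param arousal Numeric vector, one latent arousal value per condition.
#' @return Data frame with columns `outcome` and `reaction_time_s` (NA for
#'   non-response trials).
#' @export
simulate_behavior <- function(conditions, config, arousal) {
  stopifnot(nrow(conditions) == length(arousal))
  pp <- config$psychometric_params
  rp <- config$rt_params
  p_resp <- psychometric_p(conditions$contrast_pct, pp)
  responded <- runif(nrow(conditions)) < p_resp
  probe <- conditions$contrast_pct == 0
  outcome <- ifelse(probe,
                    ifelse(responded, "false_alarm", "correct_rejection"),
                    ifelse(responded, "hit", "miss"))
  nr <- naka_rushton(conditions$contrast_pct, config$contrast_semisaturation,
                     config$contrast_exponent)
  rt <- rp$base - rp$contrast_speedup * nr - rp$arousal_speedup * arousal +
    stats::rexp(nrow(conditions), rate = 1 / rp$jitter)
  rt <- pmin(pmax(rt, 0.05), 3.0)
  rt[!responded] <- NA_real_
  data.frame(outcome = outcome, reaction_time_s = rt)
}

#' Generate a synthetic session with ground truth
#'
#' Deterministic given `config$seed`. See [synth_config()] for the
#' generative model. Returns both the session (raw soma and neuropil
#' fluorescence plus trial table) and the generator's latent state for
#' parameter-recovery tests.
#'
#' @param config A `hetpop_synth_config`.
#' @return List with elements `session` (a `hetpop_session`) and `truth`
#'   (preferred orientations, hit-pattern vector, per-trial arousal, hit
#'   flags, per-trial gain matrix, per-trial pre-stimulus offsets).
#' @export
generate_session <- function(config = synth_config()) {
  stopifnot(inherits(config, "hetpop_synth_config"))
  set.seed(config$seed)
  n <- config$n_neurons
  fr <- config$frame_rate
  dt <- 1 / fr

  # trial schedule: every block holds all 48 conditions in random order
  dirs <- task_directions()
  cons <- task_contrasts()
  grid <- expand.grid(direction_deg = dirs, contrast_pct = cons)
  trials <- do.call(rbind, lapply(seq_len(config$n_blocks), function(b) {
    g <- grid[sample.int(nrow(grid)), ]
    g$block_index <- b
    g
  }))
  rownames(trials) <- NULL
  n_tr <- nrow(trials)
  trials$trial_index <- seq_len(n_tr) - 1L

  # latent arousal: standardised AR(1) across trials
  rho <- config$arousal_autocorr
  ar_noise <- rnorm(n_tr)
  arousal <- numeric(n_tr)
  arousal[1] <- ar_noise[1]
  for (t in seq_len(n_tr)[-1]) {
    arousal[t] <- rho * arousal[t - 1] + sqrt(1 - rho^2) * ar_noise[t]
  }

  beh <- simulate_behavior(trials, config, arousal)
  trials$outcome <- beh$outcome
  trials$reaction_time_s <- beh$reaction_time_s

  # frame layout: ITI (uniform 10-12 s) before each onset; stimulus window
  # ends at the response for response trials, else after the full 3 s
  iti_s <- runif(n_tr, 10, 12)
  stim_dur_s <- ifelse(is.finite(trials$reaction_time_s),
                       trials$reaction_time_s, 3.0)
  stim_frames <- pmax(1L, as.integer(round(stim_dur_s * fr)))
  onset <- integer(n_tr)
  cursor <- 0L
  for (t in seq_len(n_tr)) {
    cursor <- cursor + as.integer(round(iti_s[t] * fr))
    onset[t] <- cursor
    cursor <- cursor + stim_frames[t]
  }
  n_fr <- cursor + as.integer(round(5 * fr))
  trials$onset_frame <- onset
  trials$offset_frame <- onset + stim_frames

  # tuning: preferred orientations spread over the 4 axes
  pref <- task_orientations()[(seq_len(n) - 1L) %% 4L + 1L]
  kappa <- config$tuning_concentration
  tuning_of <- function(theta) {
    exp(kappa * (cos(2 * (theta - pref) * pi / 180) - 1))
  }
  nr_gain <- naka_rushton(trials$contrast_pct, config$contrast_semisaturation,
                          config$contrast_exponent)
  hit_pattern <- rnorm(n)
  hit_pattern <- (hit_pattern - mean(hit_pattern)) / sd(hit_pattern)

  # per-trial per-neuron drive components; log-normal gains have mean
  # exactly 1, so gain-spread differences change dispersion, not the mean
  is_hit <- trials$outcome == "hit"
  gain_sd <- ifelse(is_hit, config$hit_gain_spread, config$miss_gain_spread)
  gains <- matrix(rnorm(n * n_tr), n, n_tr)
  gains <- exp(sweep(gains, 2, gain_sd, `*`) -
                 matrix(gain_sd^2 / 2, n, n_tr, byrow = TRUE))
  common_gain <- pmax(0, 1 + config$common_gain_sd * rnorm(n_tr))
  prestim_scale <- config$prestim_sd *
    exp(config$arousal_dispersion_gain * arousal)
  prestim_offsets <- matrix(rnorm(n * n_tr), n, n_tr)
  prestim_offsets <- sweep(prestim_offsets, 2, prestim_scale, `*`)

  b0 <- config$baseline_drive
  drive <- matrix(b0, n, n_fr)
  ori <- fold_direction(trials$direction_deg)
  pre_frames <- as.integer(round(3.0 * fr))
  for (t in seq_len(n_tr)) {
    sf <- (onset[t] + 1):(onset[t] + stim_frames[t])
    evoked <- if (trials$contrast_pct[t] > 0) {
      common_gain[t] * config$response_amp * tuning_of(ori[t]) * nr_gain[t]
    } else 0
    amp <- gains[, t] * (b0 + evoked)
    if (is_hit[t]) {
      amp <- amp + config$hit_mean_boost +
        config$hit_pattern_strength * hit_pattern
    }
    drive[, sf] <- amp
    pf <- max(1L, onset[t] - pre_frames + 1L):onset[t]
    drive[, pf] <- drive[, pf] + prestim_offsets[, t]
  }

  # calcium dynamics: exponential smoothing (unit-gain single-exponential
  # kernel), then fluorescence with multiplicative baseline and noise
  lambda <- exp(-dt / config$calcium_tau)
  signal <- t(apply(drive, 1, function(x) {
    as.numeric(stats::filter((1 - lambda) * x, lambda, method = "recursive"))
  }))
  f0 <- runif(n, 90, 110)
  soma_true <- f0 * (1 + signal) +
    f0 * config$noise_sd * matrix(rnorm(n * n_fr), n, n_fr)

  # neuropil: shared slow background + bleed of the mean population drive,
  # observed on dim annuli (somata stay brighter, so the discriminability
  # ratio sits comfortably above 0.5 as in stable recordings); each soma
  # picks up the neuropil's fractional signal scaled by the contamination
  # ratio and its own brightness
  bg <- as.numeric(stats::filter(rnorm(n_fr, 0, 0.02), 0.98,
                                 method = "recursive"))
  np_signal <- 0.3 * colMeans(signal) + bg
  np_frac <- matrix(rep(np_signal, each = n), n, n_fr) +
    0.5 * config$noise_sd * matrix(rnorm(n * n_fr), n, n_fr)
  f0_np <- runif(n, 20, 32)
  neuropil <- f0_np * (1 + np_frac)
  contam <- runif(n, config$neuropil_contamination[1],
                  config$neuropil_contamination[2])
  soma <- soma_true + f0 * contam * np_frac

  trials <- trials[, c("trial_index", "direction_deg", "contrast_pct",
                       "onset_frame", "offset_frame", "outcome",
                       "reaction_time_s", "block_index")]
  session <- session_data(fr, soma, trials, neuropil)
  truth <- list(preferred_orientation = pref,
                hit_pattern_vector = hit_pattern,
                common_gain = common_gain,
                arousal_trace = arousal,
                true_hit_flags = is_hit,
                gains = gains,
                prestim_offsets = prestim_offsets,
                contamination = contam)
  list(session = session, truth = truth)
}
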