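#' Sliding-baseline dF/F0
#'
#' For each frame the baseline F0 is the mean of the lowest 50% of raw
#' fluorescence values in a centred window (default 30 s), truncated at the
#' recording edges; dF/F0 = (F - F0) / F0. Neurons whose baseline is not
#' strictly positive anywhere are flagged (their dF/F values are NaN at the
#' degenerate frames).
#'
#' @param fluorescence Matrix `[n_neurons x n_frames]` of raw fluorescence.
#' @param frame_rate Frames per second.
#' @param baseline_window_s Window width in seconds.
#' @return Matrix of dF/F0 values with attribute `flagged_neurons` (integer
#'   indices of neurons with a nonpositive baseline somewhere).
#' @export
compute_dff <- function(fluorescence, frame_rate, baseline_window_s = 30) {
  stopifnot(is.matrix(fluorescence), frame_rate > 0, baseline_window_s > 0)
  w <- round(baseline_window_s * frame_rate)
  if (w >= ncol(fluorescence) * 2) {
    # window covers the whole recording at every frame; still valid
    w <- ncol(fluorescence) * 2
  }
  h <- as.integer(floor(w / 2))
  f0 <- .sliding_lower_mean(fluorescence, h)
  dff <- (fluorescence - f0) / f0
  bad <- which(apply(f0, 1, function(x) any(x <= 0)))
  if (length(bad) > 0) {
    dff[f0 <= 0] <- NaN
    warning("nonpositive baseline for neuron(s): ", paste(bad, collapse = ", "))
  }
  attr(dff, "flagged_neurons") <- bad
  dff
}

#' Neuropil subtraction
#'
#' Per neuron, the Pearson correlation r between somatic and surrounding
#' neuropil fluorescence is computed over all frames and the soma trace is
#' corrected frame-wise as `F_corr = F_soma - r * F_neuropil`.
#'
#' @param soma Matrix `[n x F]` of somatic fluorescence.
#' @param neuropil Matched neuropil matrix.
#' @return Corrected matrix with attribute `r` (per-neuron correlation;
#'   0 for zero-variance neuropil traces, with a warning).
#' @export
neuropil_correct <- function(soma, neuropil) {
  stopifnot(identical(dim(soma), dim(neuropil)))
  r <- vapply(seq_len(nrow(soma)), function(i) {
    if (sd(neuropil[i, ]) == 0 || sd(soma[i, ]) == 0) NA_real_
    else cor(soma[i, ], neuropil[i, ])
  }, numeric(1))
  if (anyNA(r)) {
    warning("zero-variance trace for neuron(s): ",
            paste(which(is.na(r)), collapse = ", "), "; r set to 0")
    r[is.na(r)] <- 0
  }
  corrected <- soma - r * neuropil
  attr(corrected, "r") <- r
  corrected
}

#' Soma/neuropil discriminability QC
#'
#' Per frame, the discriminability ratio `D_r = F_soma / (F_soma +
#' F_neuropil)` quantifies how well a neuron stands out from its
#' surroundings; `D_r = 0.5` means equal luminance. For each neuron the
#' longest contiguous epoch at or below threshold is measured; neurons with
#' an epoch longer than 1.0 s are flagged as unstable.
#'
#' @param soma,neuropil Matched fluorescence matrices.
#' @param frame_rate Frames per second.
#' @param threshold Discriminability threshold (default 0.5).
#' @param max_epoch_s Flagging threshold on the longest sub-threshold epoch.
#' @return Data frame with per-neuron `max_epoch_s` and `flagged`, plus the
#'   full `D_r` matrix as attribute `dr`.
#' @export
discriminability_qc <- function(soma, neuropil, frame_rate,
                                threshold = 0.5, max_epoch_s = 1.0) {
  stopifnot(identical(dim(soma), dim(neuropil)), frame_rate > 0)
  dr <- soma / (soma + neuropil)
  max_epoch <- vapply(seq_len(nrow(dr)), function(i) {
    below <- dr[i, ] <= threshold
    if (!any(below)) return(0)
    runs <- rle(below)
    max(runs$lengths[runs$values]) / frame_rate
  }, numeric(1))
  out <- data.frame(neuron = seq_len(nrow(dr)),
                    max_epoch_s = max_epoch,
                    flagged = max_epoch > max_epoch_s)
  attr(out, "dr") <- dr
  out
}

#' Extract per-trial mean responses
#'
#' Builds the neurons x trials response matrix: each entry is the mean
#' dF/F0 over the trial's analysis interval. Response trials faster than
#' the fast-lick threshold (default 150 ms) are excluded. To equalise
#' signal-to-noise between hits and misses, every miss trial's analysis
#' interval is truncated to a duration drawn (reproducibly, from
#' `config$rng_seed`) from the reaction-time distribution of same-contrast
#' hit trials; correct rejections draw from the pooled hit distribution.
#' If a contrast has no hit trials its misses draw from the pooled hit
#' distribution as well.
#'
#' @param session A `hetpop_session`.
#' @param dff dF/F0 matrix from [compute_dff()].
#' @param config An [analysis_config()].
#' @return Object of class `hetpop_responses`: `values` (matrix
#'   `[n_neurons x n_kept_trials]`), `trials` (kept trial records with
#'   `orientation_deg` and `analysis_offset_frame`), `excluded` (dropped
#'   trials with reasons), `frame_rate`.
#' @export
extract_trial_responses <- function(session, dff, config = analysis_config()) {
  validate_session(session)
  stopifnot(identical(dim(dff), dim(session$soma)))
  tr <- session$trials
  fr <- session$frame_rate
  tr$orientation_deg <- fold_direction(tr$direction_deg)

  excluded <- rep(NA_character_, nrow(tr))
  fast <- is.finite(tr$reaction_time_s) &
    tr$reaction_time_s < config$rt_exclusion_s
  excluded[fast] <- "fast_lick"

  # seeded miss-duration matching
  rs <- local_rng(config$rng_seed, 101L)
  on.exit(restore_rng(rs))
  hit_rts <- split(tr$reaction_time_s[tr$outcome == "hit" & !fast],
                   tr$contrast_pct[tr$outcome == "hit" & !fast])
  pooled_rts <- tr$reaction_time_s[tr$outcome == "hit" & !fast]
  analysis_offset <- tr$offset_frame
  for (i in seq_len(nrow(tr))) {
    if (!is.na(excluded[i])) next
    if (tr$outcome[i] %in% c("miss", "correct_rejection")) {
      pool <- if (tr$outcome[i] == "miss") {
        hit_rts[[as.character(tr$contrast_pct[i])]]
      } else NULL
      if (is.null(pool) || length(pool) == 0) pool <- pooled_rts
      if (length(pool) == 0) next  # no hits at all: keep full window
      dur <- pool[sample.int(length(pool), 1)]
      analysis_offset[i] <- min(tr$offset_frame[i],
                                tr$onset_frame[i] + max(1L, round(dur * fr)))
    }
  }
  tr$analysis_offset_frame <- analysis_offset

  keep <- which(is.na(excluded))
  values <- vapply(keep, function(i) {
    idx <- (tr$onset_frame[i] + 1L):tr$analysis_offset_frame[i]
    rowMeans(dff[, idx, drop = FALSE])
  }, numeric(nrow(dff)))
  structure(list(values = values,
                 trials = tr[keep, , drop = FALSE],
                 excluded = cbind(tr[!is.na(excluded), , drop = FALSE],
                                  reason = excluded[!is.na(excluded)]),
                 frame_rate = fr),
            class = "hetpop_responses")
}

#' Z-score trial responses per neuron
#'
#' Standardises each neuron's responses to SD units, either over all trial
#' types (`global`, the default) or within each contrast stratum
#' (`per_contrast`). Sample SD (n-1 divisor) is used. Neurons with zero
#' variance in any stratum are dropped with a warning.
#'
#' @param responses A `hetpop_responses` object (or bare matrix).
#' @param scope `"global"` or `"per_contrast"`.
#' @param contrasts Required when `scope = "per_contrast"` and `responses`
#'   is a bare matrix: per-trial contrast labels.
#' @return Object of class `hetpop_zscores`: `values` (matrix in SD units),
#'   `scope`, `mu`/`sigma` (per neuron, or per neuron x contrast),
#'   `kept_neurons` (row indices into the input).
#' @export
zscore_responses <- function(responses, scope = c("global", "per_contrast"),
                             contrasts = NULL) {
  scope <- match.arg(scope)
  if (inherits(responses, "hetpop_responses")) {
    values <- responses$values
    contrasts <- responses$trials$contrast_pct
  } else {
    values <- responses
  }
  stopifnot(is.matrix(values), ncol(values) >= 2)
  if (scope == "global") {
    mu <- rowMeans(values)
    sigma <- apply(values, 1, sd)
    keep <- sigma > 0
    z <- (values[keep, , drop = FALSE] - mu[keep]) / sigma[keep]
  } else {
    if (is.null(contrasts)) stop("per_contrast scope needs contrast labels")
    strata <- split(seq_len(ncol(values)), contrasts)
    thin <- vapply(strata, length, integer(1)) < 2
    if (any(thin)) {
      stop("contrast stratum with fewer than 2 trials: ",
           paste(names(strata)[thin], collapse = ", "))
    }
    mu <- sapply(strata, function(ix) rowMeans(values[, ix, drop = FALSE]))
    sigma <- sapply(strata, function(ix) apply(values[, ix, drop = FALSE], 1, sd))
    keep <- apply(sigma, 1, function(s) all(s > 0))
    z <- values
    for (s in names(strata)) {
      ix <- strata[[s]]
      z[, ix] <- (values[, ix] - mu[, s]) / sigma[, s]
    }
    z <- z[keep, , drop = FALSE]
  }
  if (!all(keep)) {
    warning("dropped zero-variance neuron(s): ",
            paste(which(!keep), collapse = ", "))
  }
  structure(list(values = z, scope = scope, mu = mu, sigma = sigma,
                 kept_neurons = which(keep)),
            class = "hetpop_zscores")
}

#' Assign preferred orientations with a block-consistency filter
#'
#' Each neuron's preferred orientation is the one of the 4 axes yielding
#' the highest mean response (all nonzero contrasts pooled). Preferences
#' are also computed per repetition block; a neuron is consistently tuned
#' iff the fraction of blocks whose preference differs from the modal
#' block preference is at most 1/3. Argmax ties break toward the lowest
#' orientation.
#'
#' @param responses A `hetpop_responses` object.
#' @return Data frame per neuron: `preferred_orientation`, `consistent`;
#'   attribute `block_preferences` (neurons x blocks matrix).
#' @export
assign_preferred_orientation <- function(responses) {
  stopifnot(inherits(responses, "hetpop_responses"))
  tr <- responses$trials
  values <- responses$values
  stim <- tr$contrast_pct > 0
  oris <- task_orientations()

  pref_of <- function(cols) {
    if (length(cols) == 0) return(rep(NA_real_, nrow(values)))
    means <- sapply(oris, function(o) {
      ix <- cols[tr$orientation_deg[cols] == o]
      if (length(ix) == 0) return(rep(-Inf, nrow(values)))
      rowMeans(values[, ix, drop = FALSE])
    })
    oris[apply(means, 1, which.max)]  # which.max takes the first (lowest) on ties
  }

  overall <- pref_of(which(stim))
  blocks <- sort(unique(tr$block_index))
  block_pref <- sapply(blocks, function(b) pref_of(which(stim & tr$block_index == b)))
  if (is.null(dim(block_pref))) block_pref <- matrix(block_pref, ncol = length(blocks))
  modal <- apply(block_pref, 1, function(p) {
    tab <- table(factor(p, levels = oris))
    oris[which.max(tab)]
  })
  disagree <- rowMeans(block_pref != modal)
  out <- data.frame(neuron = seq_len(nrow(values)),
                    preferred_orientation = overall,
                    consistent = disagree <= 1 / 3)
  attr(out, "block_preferences") <- block_pref
  attr(out, "modal_preference") <- modal
  out
}
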