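#' Per-trial population heterogeneity
#'
#' For each trial t the z-scored population vector z_t defines a
#' heterogeneity matrix `H_t = |z_t - z_t^T|` of absolute pairwise
#' differences; the scalar heterogeneity h_t is the mean of H_t over the
#' n(n-1)/2 unique neuron pairs — the mean distance in activation level
#' (SD units) between neurons within one trial. Computed here via the
#' sorted-vector identity, which equals the brute-force pair loop exactly.
#'
#' @param z A `hetpop_zscores` object or matrix `[n_neurons x n_trials]`.
#' @return Numeric vector, one heterogeneity value (>= 0) per trial.
#' @export
heterogeneity <- function(z) {
  zm <- values_matrix(z)
  stopifnot(is.matrix(zm), nrow(zm) >= 2)
  apply(zm, 2, mean_abs_pairwise_diff)
}

#' Heterogeneity matrix of a single trial
#'
#' @param z_t Numeric vector of z-scored responses for one trial.
#' @return Symmetric matrix of absolute pairwise differences, zero diagonal.
#' @export
heterogeneity_matrix <- function(z_t) {
  stopifnot(length(z_t) >= 2)
  abs(outer(z_t, z_t, `-`))
}

#' Multidimensional heterogeneity (distance to the main diagonal)
#'
#' Treats each trial's population response as a point in n-dimensional
#' neural space and measures the Euclidean distance from that point to its
#' projection on the all-equal ("main") diagonal:
#' `sqrt(sum_i (r_i - mean(r))^2)`. On z-scored data this is nearly
#' equivalent to the pairwise definition ([heterogeneity()]), with
#' across-trial Pearson correlations above 0.9.
#'
#' @param m Matrix `[n_neurons x n_trials]` (raw dF/F or z-scores) or a
#'   `hetpop_zscores`/`hetpop_responses` object.
#' @return Numeric vector, one distance per trial.
#' @export
multidim_heterogeneity <- function(m) {
  mm <- values_matrix(m)
  stopifnot(is.matrix(mm), nrow(mm) >= 2)
  sqrt(colSums(sweep(mm, 2, colMeans(mm))^2))
}

#' Instantaneous Pearson-like correlation per trial
#'
#' For each unique neuron pair (x, y) and trial t the z-score product
#' `Z_x,t * Z_y,t` is an instantaneous analogue of a Pearson correlation
#' term: averaging it over trials recovers the conventional pairwise
#' Pearson correlation, while averaging over pairs within one trial gives a
#' per-trial population correlation estimate (the Pearson-like correlation,
#' unbounded outside `[-1, 1]`). The SD over pairs estimates the spread of
#' the instantaneous pairwise correlation distribution.
#'
#' @param z A `hetpop_zscores` object or z-score matrix.
#' @return List with numeric per-trial vectors `mean` and `spread`.
#' @export
pearson_like <- function(z) {
  zm <- values_matrix(z)
  n <- nrow(zm)
  stopifnot(is.matrix(zm), n >= 2)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  prod_mat <- zm[pairs[, 1], , drop = FALSE] * zm[pairs[, 2], , drop = FALSE]
  list(mean = colMeans(prod_mat),
       spread = if (nrow(prod_mat) > 1) apply(prod_mat, 2, sd)
                else rep(0, ncol(prod_mat)))
}

#' Comparator metrics: per-trial variance and sparseness (kurtosis)
#'
#' `variance_metric` is the sample variance across neurons per trial;
#' `sparseness_kurtosis` is the raw fourth standardised moment (a Gaussian
#' population gives 3). Kurtosis requires at least 4 neurons and is NaN
#' (with a warning) for zero-variance trials.
#'
#' @param z A `hetpop_zscores` object or matrix.
#' @return Numeric vector per trial.
#' @export
variance_metric <- function(z) {
  zm <- values_matrix(z)
  stopifnot(nrow(zm) >= 2)
  apply(zm, 2, var)
}

#' @rdname variance_metric
#' @export
sparseness_kurtosis <- function(z) {
  zm <- values_matrix(z)
  stopifnot(nrow(zm) >= 4)
  out <- apply(zm, 2, function(x) {
    m2 <- mean((x - mean(x))^2)
    if (m2 == 0) return(NaN)
    mean((x - mean(x))^4) / m2^2
  })
  if (any(is.nan(out))) warning("kurtosis undefined for zero-variance trial(s)")
  out
}

gaussian_window_weights <- function(m, center, sd_frames) {
  w <- exp(-((seq_len(m) - center)^2) / (2 * sd_frames^2))
  w / sum(w)
}

#' Sliding-window pairwise correlations within trials
#'
#' A conventional time-domain comparator to the Pearson-like correlation:
#' per trial, a Gaussian-weighted windowed Pearson correlation (kernel
#' full-width-half-maximum = `time_scale`, default 1.0 s) is computed for
#' each neuron pair at each in-trial frame and averaged over frames; the
#' mean and SD over pairs are returned per trial. Windows are truncated
#' (and renormalised) at trial edges; trials shorter than the kernel are
#' still computed and flagged.
#'
#' @param dff dF/F0 matrix `[n_neurons x n_frames]`.
#' @param responses A `hetpop_responses` object (for trial intervals).
#' @param time_scale Kernel FWHM in seconds.
#' @param max_pairs Optional cap on the number of neuron pairs (random but
#'   seed-stable subsample) to bound cost on large populations.
#' @return List of per-trial vectors `mean` and `spread`, plus
#'   `short_trials` (indices of trials shorter than the kernel FWHM).
#' @export
sliding_window_correlation <- function(dff, responses, time_scale = 1.0,
                                       max_pairs = Inf) {
  stopifnot(time_scale > 0)
  tr <- responses$trials
  fr <- responses$frame_rate
  n <- nrow(dff)
  sd_frames <- time_scale * fr / (2 * sqrt(2 * log(2)))  # FWHM -> SD
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (is.finite(max_pairs) && nrow(pairs) > max_pairs) {
    rs <- local_rng(1L, 77L); on.exit(restore_rng(rs))
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  }
  fwhm_frames <- round(time_scale * fr)
  res <- lapply(seq_len(nrow(tr)), function(t) {
    idx <- (tr$onset_frame[t] + 1L):tr$analysis_offset_frame[t]
    x <- dff[, idx, drop = FALSE]
    m <- ncol(x)
    # weighted moments at every frame center via kernel matrix [m x m]
    K <- sapply(seq_len(m), function(c) gaussian_window_weights(m, c, sd_frames))
    ex <- x %*% K
    ex2 <- (x^2) %*% K
    vx <- pmax(ex2 - ex^2, 0)
    xi <- x[pairs[, 1], , drop = FALSE]
    xj <- x[pairs[, 2], , drop = FALSE]
    exy <- (xi * xj) %*% K
    cov_ij <- exy - ex[pairs[, 1], , drop = FALSE] * ex[pairs[, 2], , drop = FALSE]
    den <- sqrt(vx[pairs[, 1], , drop = FALSE] * vx[pairs[, 2], , drop = FALSE])
    r <- cov_ij / den
    r[!is.finite(r)] <- NA
    rowMeans(r, na.rm = TRUE)  # per-pair mean over in-trial frames
  })
  list(mean = vapply(res, function(p) mean(p, na.rm = TRUE), numeric(1)),
       spread = vapply(res, function(p) if (length(p) > 1) sd(p, na.rm = TRUE) else 0,
                       numeric(1)),
       short_trials = which(tr$analysis_offset_frame - tr$onset_frame < fwhm_frames))
}

#' Frame-resolved metric timecourses around stimulus onset
#'
#' Computes a per-frame population metric (mean dF/F0 or heterogeneity)
#' for each trial, aligned to stimulus onset, from `-prestim_window_s`
#' before onset to the 3-s stimulus window end. Per-frame z-scores reuse
#' the trial-level per-neuron mean and SD, so frame- and trial-resolved
#' heterogeneity share one scale. Frames after the trial's analysis
#' interval (and pre-stimulus frames missing at the recording start) are NA.
#'
#' @param dff dF/F0 matrix.
#' @param responses A `hetpop_responses` object.
#' @param zscores The `hetpop_zscores` for the same responses (provides
#'   per-neuron `mu` and `sigma`; global scope required).
#' @param metric `"heterogeneity"` or `"mean_dff"`.
#' @param prestim_window_s Pre-stimulus window, s.
#' @return Matrix `[n_trials x n_frames_aligned]` with attribute
#'   `onset_index` (column of stimulus onset) and `frame_rate`.
#' @export
metric_timecourse <- function(dff, responses, zscores = NULL,
                              metric = c("heterogeneity", "mean_dff"),
                              prestim_window_s = 3.0) {
  metric <- match.arg(metric)
  tr <- responses$trials
  fr <- responses$frame_rate
  pre <- round(prestim_window_s * fr)
  stim <- round(3.0 * fr)
  if (metric == "heterogeneity") {
    if (is.null(zscores) || zscores$scope != "global") {
      stop("heterogeneity timecourse needs global-scope zscores for mu/sigma")
    }
    keep <- zscores$kept_neurons
    mu <- zscores$mu[keep]
    sigma <- zscores$sigma[keep]
  }
  out <- matrix(NA_real_, nrow(tr), pre + stim)
  for (t in seq_len(nrow(tr))) {
    f0 <- tr$onset_frame[t] - pre + 1L
    f1 <- tr$analysis_offset_frame[t]
    cols_in <- max(1L, f0):f1
    cols_out <- cols_in - f0 + 1L
    seg <- dff[, cols_in, drop = FALSE]
    vals <- if (metric == "mean_dff") {
      colMeans(seg)
    } else {
      zseg <- (seg[keep, , drop = FALSE] - mu) / sigma
      apply(zseg, 2, mean_abs_pairwise_diff)
    }
    out[t, cols_out] <- vals
  }
  attr(out, "onset_index") <- pre + 1L
  attr(out, "frame_rate") <- fr
  out
}

#' Pre-stimulus population metrics per trial
#'
#' For each trial, averages each neuron's dF/F0 over the pre-stimulus
#' window (default 3 to 0 s before onset) and summarises the resulting
#' population vector two ways: its mean (pre-stimulus population dF/F0)
#' and its heterogeneity after z-scoring with the trial-level per-neuron
#' statistics.
#'
#' @inheritParams metric_timecourse
#' @return Data frame: `trial_index`, `prestim_mean_dff`,
#'   `prestim_heterogeneity`.
#' @export
prestim_metrics <- function(dff, responses, zscores,
                            prestim_window_s = 3.0) {
  stopifnot(zscores$scope == "global")
  tr <- responses$trials
  fr <- responses$frame_rate
  pre <- round(prestim_window_s * fr)
  keep <- zscores$kept_neurons
  mu <- zscores$mu[keep]
  sigma <- zscores$sigma[keep]
  out <- lapply(seq_len(nrow(tr)), function(t) {
    cols <- max(1L, tr$onset_frame[t] - pre + 1L):tr$onset_frame[t]
    v <- rowMeans(dff[, cols, drop = FALSE])
    zv <- (v[keep] - mu) / sigma
    c(mean_dff = mean(v), het = mean_abs_pairwise_diff(zv))
  })
  out <- do.call(rbind, out)
  data.frame(trial_index = tr$trial_index,
             prestim_mean_dff = out[, "mean_dff"],
             prestim_heterogeneity = out[, "het"])
}
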