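#' Hit-modulation matrix
#'
#' For every hit trial t and neuron i, the hit-modulation index is the
#' neuron's response z-scored against miss trials of the same stimulus type
#' (identical orientation and contrast):
#' `Psi_i,t = (R_i,t - mu_miss,c,theta) / sigma_miss,c,theta` (sample SD).
#' Strata with fewer than 2 miss trials (or zero miss SD for a neuron) are
#' dropped with a warning; only test contrasts are used by default.
#'
#' @param responses A `hetpop_responses` object.
#' @param contrasts Contrasts to include (default the test contrasts).
#' @return Object of class `hetpop_hitmod`: `values` (matrix
#'   `[n_neurons x n_hit_trials]`), `conditions` (orientation/contrast per
#'   column), `dropped_strata`.
#' @export
hit_modulation_matrix <- function(responses, contrasts = test_contrasts()) {
  tr <- responses$trials
  values <- responses$values
  use <- tr$contrast_pct %in% contrasts
  strata <- unique(tr[use, c("orientation_deg", "contrast_pct")])
  cols <- list(); cond <- list(); dropped <- list()
  for (s in seq_len(nrow(strata))) {
    o <- strata$orientation_deg[s]; ct <- strata$contrast_pct[s]
    in_s <- use & tr$orientation_deg == o & tr$contrast_pct == ct
    miss_ix <- which(in_s & tr$outcome == "miss")
    hit_ix <- which(in_s & tr$outcome == "hit")
    if (length(miss_ix) < 2 || length(hit_ix) == 0) {
      dropped[[length(dropped) + 1]] <- data.frame(
        orientation_deg = o, contrast_pct = ct,
        reason = if (length(miss_ix) < 2) "fewer_than_2_misses" else "no_hits")
      next
    }
    mu <- rowMeans(values[, miss_ix, drop = FALSE])
    sigma <- apply(values[, miss_ix, drop = FALSE], 1, sd)
    sigma[sigma == 0] <- NA  # neuron undefined in this stratum
    psi <- (values[, hit_ix, drop = FALSE] - mu) / sigma
    cols[[length(cols) + 1]] <- psi
    cond[[length(cond) + 1]] <- data.frame(
      trial_index = tr$trial_index[hit_ix], orientation_deg = o,
      contrast_pct = ct)
  }
  if (length(dropped) > 0) {
    warning(length(dropped), " stimulus stratum/strata dropped from the ",
            "hit-modulation matrix")
  }
  if (length(cols) == 0) stop("no stratum with >= 2 miss trials and a hit trial")
  structure(list(values = do.call(cbind, cols),
                 conditions = do.call(rbind, cond),
                 dropped_strata = if (length(dropped)) do.call(rbind, dropped)
                                  else NULL),
            class = "hetpop_hitmod")
}

hitmod_approximations <- function(psi) {
  by_neuron <- matrix(rowMeans(psi), nrow(psi), ncol(psi))
  by_trial <- matrix(colMeans(psi), nrow(psi), ncol(psi), byrow = TRUE)
  list(neuron = by_neuron, trial = by_trial, both = by_neuron + by_trial)
}

hitmod_r2 <- function(psi, approx) {
  ss_tot <- sum(psi^2)  # uncentered total sum of squares
  if (ss_tot == 0) stop("degenerate hit-modulation matrix (all zeros)")
  vapply(approx, function(a) 1 - sum((psi - a)^2) / ss_tot, numeric(1))
}

shuffle_psi <- function(psi, mode) {
  n <- nrow(psi); m <- ncol(psi)
  switch(mode,
         neuron = apply(psi, 2, sample),              # permute neurons per trial
         trial = t(apply(psi, 1, sample)),            # permute trials per neuron
         both = matrix(sample(psi), n, m))            # full scramble
}

#' Decompose the hit-modulation matrix
#'
#' Approximates the hit-modulation matrix by neuron identity (each row's
#' mean over trials), by trial-by-trial population fluctuations (each
#' column's mean over neurons), or by both (sum of the two approximation
#' matrices), and quantifies each approximation's explained variance
#' `R^2 = 1 - SS_res / SS_tot` with SS_tot the sum of all squared entries.
#' Significance is assessed against shuffle nulls (neuron identities
#' permuted within trials, trial identities within neurons, or both) with
#' the criterion real `R^2 >=` shuffle mean + 2 shuffle SD. Additionally,
#' each neuron is tested for consistent hit modulation (two-sided one-sample
#' t-test of its row against 0) and the fraction of significant neurons is
#' compared to the same 2-SD criterion under the full-scramble null.
#'
#' @param hitmod A `hetpop_hitmod` object.
#' @param iterations Number of shuffle iterations (>= 100; default 1000).
#' @param alpha Per-neuron test level.
#' @param center_grand_mean If TRUE, the "both" approximation subtracts the
#'   grand mean once (the plain sum counts it twice); default FALSE keeps
#'   the literal matrix sum.
#' @param rng_seed Seed for the shuffle null.
#' @return List: `r2` (named: neuron/trial/both), `shuffle_mean`,
#'   `shuffle_sd`, `significant` (logical per mode), `frac_significant_neurons`,
#'   `frac_shuffle_mean`, `frac_shuffle_sd`, `frac_significant`.
#' @export
decompose_hit_modulation <- function(hitmod, iterations = 1000L, alpha = 0.05,
                                     center_grand_mean = FALSE, rng_seed = 1L) {
  stopifnot(inherits(hitmod, "hetpop_hitmod"), iterations >= 100)
  psi <- hitmod$values
  keep <- stats::complete.cases(psi)
  psi <- psi[keep, , drop = FALSE]
  approx <- hitmod_approximations(psi)
  if (center_grand_mean) approx$both <- approx$both - mean(psi)
  r2 <- hitmod_r2(psi, approx)

  row_p <- function(row) {
    if (sd(row) == 0) return(if (mean(row) == 0) 1 else 0)
    t.test(row, mu = 0)$p.value
  }
  neuron_p <- apply(psi, 1, row_p)
  frac_sig <- mean(neuron_p < alpha)

  rs <- local_rng(rng_seed, 202L)
  on.exit(restore_rng(rs))
  modes <- c("neuron", "trial", "both")
  shuf_r2 <- matrix(NA_real_, iterations, 3, dimnames = list(NULL, modes))
  shuf_frac <- numeric(iterations)
  for (it in seq_len(iterations)) {
    for (mode in modes) {
      ps <- shuffle_psi(psi, mode)
      ap <- hitmod_approximations(ps)[[mode]]
      if (center_grand_mean && mode == "both") ap <- ap - mean(ps)
      shuf_r2[it, mode] <- 1 - sum((ps - ap)^2) / sum(ps^2)
    }
    ps <- shuffle_psi(psi, "both")
    shuf_frac[it] <- mean(apply(ps, 1, row_p) < alpha)
  }
  sh_mean <- colMeans(shuf_r2)
  sh_sd <- apply(shuf_r2, 2, sd)
  list(r2 = r2,
       shuffle_mean = sh_mean,
       shuffle_sd = sh_sd,
       significant = r2 >= sh_mean + 2 * sh_sd,
       frac_significant_neurons = frac_sig,
       frac_shuffle_mean = mean(shuf_frac),
       frac_shuffle_sd = sd(shuf_frac),
       frac_significant = frac_sig >= mean(shuf_frac) + 2 * sd(shuf_frac),
       n_neurons_used = nrow(psi))
}
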