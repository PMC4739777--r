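#' Run the full analysis pipeline on one session
#'
#' Orchestrates every stage in dependency order: preprocessing (sliding
#' dF/F0, QC, trial extraction, z-scoring, tuning), per-trial population
#' metrics, hit-modulation decomposition, detection statistics (effect
#' sizes, ROC, reaction-time regression, pre-stimulus predictability,
#' pattern consistency, noise correlations, behavioural confidence
#' intervals), decoders (presence, orientation, stimulus type, single-trial
#' predictive) and response-space geometry. A failure in one analysis is
#' recorded in `$errors` and does not abort the others. All random draws
#' derive from `config$rng_seed` via per-stage sub-streams, so the report
#' is reproducible and stages remain reproducible in isolation.
#'
#' @param session A `hetpop_session`, or NULL to generate one.
#' @param synth A `hetpop_synth_config` used when `session` is NULL.
#' @param config An [analysis_config()].
#' @return A list of per-stage results (class `hetpop_report`) with
#'   elements `preprocess`, `metrics`, `hitmod`, `stats`, `decoding`,
#'   `geometry`, `config`, `errors`.
#' @export
run_full_analysis <- function(session = NULL, synth = synth_config(),
                              config = analysis_config()) {
  errors <- list()
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  if (is.null(session)) {
    gen <- generate_session(synth)
    session <- gen$session
  }

  pp <- try_stage("preprocess", {
    dff <- compute_dff(session$soma, session$frame_rate,
                       config$baseline_window_s)
    qc <- if (!is.null(session$neuropil)) {
      discriminability_qc(session$soma, session$neuropil, session$frame_rate)
    } else NULL
    neuropil_r <- if (!is.null(session$neuropil)) {
      attr(neuropil_correct(session$soma, session$neuropil), "r")
    } else NULL
    responses <- extract_trial_responses(session, dff, config)
    z_global <- zscore_responses(responses, "global")
    z_contrast <- tryCatch(zscore_responses(responses, "per_contrast"),
                           error = function(e) {
                             errors$z_per_contrast <<- conditionMessage(e)
                             NULL
                           })
    tuning <- assign_preferred_orientation(responses)
    list(dff = dff, qc = qc, neuropil_r = neuropil_r, responses = responses,
         z_global = z_global, z_contrast = z_contrast, tuning = tuning)
  })
  if (is.null(pp)) {
    return(structure(list(config = config, errors = errors),
                     class = "hetpop_report"))
  }
  responses <- pp$responses
  tr <- responses$trials

  met <- try_stage("metrics", {
    pl <- pearson_like(pp$z_global)
    list(mean_dff = colMeans(responses$values),
         heterogeneity = heterogeneity(pp$z_global),
         heterogeneity_per_contrast = if (!is.null(pp$z_contrast))
           heterogeneity(pp$z_contrast) else NULL,
         multidim_het = multidim_heterogeneity(pp$z_global),
         pearson_like_mean = pl$mean, pearson_like_spread = pl$spread,
         variance = variance_metric(pp$z_global),
         kurtosis = sparseness_kurtosis(pp$z_global),
         prestim = prestim_metrics(pp$dff, responses, pp$z_global,
                                   config$prestim_window_s))
  })

  hm <- try_stage("hitmod", {
    psi <- hit_modulation_matrix(responses)
    decomp <- decompose_hit_modulation(
      psi, iterations = config$shuffle_iterations$hitmod %||% 1000L,
      alpha = config$fdr_alpha, rng_seed = config$rng_seed)
    list(psi = psi, decomposition = decomp)
  })

  st <- try_stage("stats", {
    response_type <- split_fast_slow(responses)
    d_het <- effect_size_by_contrast(met$heterogeneity, responses)
    d_dff <- effect_size_by_contrast(met$mean_dff, responses)
    auc_het <- roc_by_contrast(met$heterogeneity, responses)
    auc_dff <- roc_by_contrast(met$mean_dff, responses)
    rt_het <- regress_metric_on_rt(met$heterogeneity, responses)
    rt_dff <- regress_metric_on_rt(met$mean_dff, responses)
    consistency <- pattern_consistency(
      responses, pp$tuning, response_type,
      iterations = config$shuffle_iterations$consistency %||% 100L,
      rng_seed = config$rng_seed)
    fast_ix <- which(response_type == "fast")
    slow_ix <- which(response_type == "slow")
    nc <- list(all = noise_correlations(responses),
               fast = noise_correlations(responses, subset = fast_ix),
               slow = noise_correlations(responses, subset = slow_ix))
    # behavioural detection check: probe vs 100% response CIs
    n0 <- sum(tr$contrast_pct == 0)
    k0 <- sum(tr$contrast_pct == 0 & tr$outcome == "false_alarm")
    n100 <- sum(tr$contrast_pct == 100)
    k100 <- sum(tr$contrast_pct == 100 & tr$outcome == "hit")
    ci0 <- clopper_pearson_ci(k0, n0)
    ci100 <- clopper_pearson_ci(k100, n100)
    # per-block pre-stimulus points per response type -> predictability
    prestim_points <- function(metric_col) {
      sapply(c("miss", "slow", "fast"), function(tt) {
        vapply(sort(unique(tr$block_index)), function(b) {
          ix <- which(response_type == tt & tr$block_index == b)
          if (length(ix) == 0) NA_real_ else mean(met$prestim[[metric_col]][ix])
        }, numeric(1))
      })
    }
    delta_for <- function(metric_col) {
      pts <- prestim_points(metric_col)
      pairs <- list(c("fast", "miss"), c("slow", "miss"), c("fast", "slow"))
      out <- lapply(pairs, function(pr) {
        a <- pts[, pr[1]]; b <- pts[, pr[2]]
        ok <- complete.cases(a, b)
        if (sum(ok) < 2) return(NULL)
        data.frame(pair = paste(pr, collapse = "_vs_"),
                   mean_delta = predictability_delta(a[ok], b[ok])$mean_delta)
      })
      do.call(rbind, out)
    }
    list(response_type = response_type,
         effect_size = list(heterogeneity = d_het, mean_dff = d_dff),
         roc = list(heterogeneity = auc_het, mean_dff = auc_dff),
         rt_regression = list(heterogeneity = rt_het, mean_dff = rt_dff),
         consistency = consistency,
         noise_correlations = nc,
         behavior_ci = list(probe = ci0, contrast100 = ci100,
                            significant_detection = ci0["upper"] < ci100["lower"]),
         predictability = list(heterogeneity = delta_for("prestim_heterogeneity"),
                               mean_dff = delta_for("prestim_mean_dff")))
  })

  dec <- try_stage("decoding", {
    presence <- decode_stimulus_presence(responses, pp$tuning)
    # psychometric curves over contrasts: decoder present-rate vs behaviour
    cons <- task_contrasts()
    beh_rate <- vapply(cons, function(ct) {
      ix <- tr$contrast_pct == ct
      mean(tr$outcome[ix] %in% c("hit", "false_alarm"))
    }, numeric(1))
    dec_rate <- vapply(cons, function(ct) {
      ix <- !is.na(presence$trials$decoded_present) &
        presence$trials$contrast_pct == ct
      mean(presence$trials$decoded_present[ix])
    }, numeric(1))
    similarity <- presence_behavior_similarity(
      dec_rate, beh_rate,
      iterations = config$shuffle_iterations$similarity %||% 1000L,
      rng_seed = config$rng_seed)
    chisq <- presence_outcome_chisq(presence$trials$decoded_present,
                                    tr$outcome)
    ori <- lapply(setdiff(task_contrasts(), 0), function(ct) {
      decode_orientation(responses, ct)
    })
    names(ori) <- setdiff(task_contrasts(), 0)
    ori <- Filter(Negate(is.null), ori)
    correct <- rep(NA, nrow(tr)); ctr <- rep(NA_real_, nrow(tr))
    for (o in ori) {
      correct[o$trial_ix] <- o$correct
      ctr[o$trial_ix] <- tr$contrast_pct[o$trial_ix]
    }
    split_dff <- decoding_vs_metric_split(correct, met$mean_dff, ctr)
    split_het <- decoding_vs_metric_split(correct, met$heterogeneity, ctr)
    stim_type <- decode_stimulus_type(responses)
    response_type <- st$response_type
    pred_het <- predictive_decode_response_type(
      met$prestim$prestim_heterogeneity, response_type)
    pred_dff <- predictive_decode_response_type(
      met$prestim$prestim_mean_dff, response_type)
    list(presence = presence, behavior_rate = beh_rate,
         decoder_rate = dec_rate, similarity = similarity, chisq = chisq,
         orientation = ori,
         orientation_accuracy = vapply(ori, `[[`, numeric(1), "accuracy"),
         metric_split = list(mean_dff = split_dff, heterogeneity = split_het),
         stimulus_type = stim_type,
         predictive = list(heterogeneity = pred_het, mean_dff = pred_dff))
  })

  geo <- try_stage("geometry", {
    ix <- which(tr$contrast_pct %in% test_contrasts() &
                  tr$outcome %in% c("hit", "miss"))
    pts <- t(responses$values[, ix, drop = FALSE])
    labs <- tr$outcome[ix]
    dist_hit <- pairwise_distances(pts, labs, "hit")
    dist_miss <- pairwise_distances(pts, labs, "miss")
    asym_hit <- mirroring_asymmetry(pts[labs == "hit", , drop = FALSE])
    asym_miss <- mirroring_asymmetry(pts[labs == "miss", , drop = FALSE])
    removal <- hitmiss_decode_after_removal(pts, labs)
    list(mean_distance = c(hit = dist_hit$mean_distance,
                           miss = dist_miss$mean_distance),
         asymmetry = c(hit = asym_hit$asymmetry, miss = asym_miss$asymmetry),
         removal_decoding = removal)
  })

  structure(list(preprocess = pp, metrics = met, hitmod = hm, stats = st,
                 decoding = dec, geometry = geo, config = config,
                 errors = errors),
            class = "hetpop_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hetpop_report <- function(x, ...) {
  stages <- setdiff(names(x), c("config", "errors"))
  done <- stages[!vapply(x[stages], is.null, logical(1))]
  cat("<hetpop_report> stages completed:", paste(done, collapse = ", "), "\n")
  if (length(x$errors) > 0) {
    cat("errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n", sep = "")
  }
  invisible(x)
}
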