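#' @useDynLib hetpop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate coef cor dist dnorm lm median p.adjust
#'   rnorm runif sd t.test var binom.test chisq.test setNames complete.cases
#' @importFrom utils read.delim write.table head tail
NULL

#' Task design constants
#'
#' The stimulus set of the go/no-go detection task: 8 drifting-grating
#' directions (45-degree steps), 6 contrasts, folding onto 4 orientations.
#'
#' @return Numeric vector of directions, contrasts or orientations in the
#'   task design.
#' @export
task_directions <- function() seq(0, 315, by = 45)

#' @rdname task_directions
#' @export
task_contrasts <- function() c(0, 0.5, 2, 8, 32, 100)

#' @rdname task_directions
#' @export
task_orientations <- function() c(0, 45, 90, 135)

#' Test contrasts (intermediate contrasts used for hit/miss comparisons)
#'
#' The two extreme contrasts (0% probe, 100%) act as anchors for behaviour
#' and decoding; hit/miss comparisons are made over the intermediate
#' contrasts 0.5, 2, 8 and 32%.
#'
#' @return Numeric vector of contrast percentages.
#' @export
test_contrasts <- function() c(0.5, 2, 8, 32)

#' Fold a drifting-grating direction onto its orientation axis
#'
#' Opposite drift directions share an orientation axis; mouse V1 neurons are
#' predominantly orientation- rather than direction-tuned, so directions are
#' folded modulo 180 degrees before tuning assignment and decoding.
#'
#' @param direction Numeric vector of directions in degrees, each in
#'   `[0, 360)`.
#' @return Orientations in degrees (`direction %% 180`).
#' @examples
#' fold_direction(c(0, 45, 225, 315))
#' @export
fold_direction <- function(direction) {
  if (any(!is.finite(direction)) || any(direction < 0) || any(direction >= 360)) {
    stop("direction must lie in [0, 360)")
  }
  direction %% 180
}

#' Analysis configuration
#'
#' Bundles the tunable preprocessing/analysis parameters. Defaults follow
#' the study design: a 30-s sliding baseline window, a 150-ms fast-lick
#' exclusion, a 3-s pre-stimulus window, and Benjamini-Hochberg FDR at 0.05.
#'
#' @param zscore_scope `"global"` (z-score each neuron over all trials) or
#'   `"per_contrast"`.
#' @param rt_exclusion_s Reaction-time exclusion threshold in seconds;
#'   responses faster than this are treated as impulsive licks.
#' @param baseline_window_s Width of the centred sliding-baseline window (s).
#' @param prestim_window_s Pre-stimulus window used for baselines and
#'   predictability analyses (s).
#' @param shuffle_iterations Named list of shuffle counts per analysis.
#' @param fdr_alpha Significance level after FDR correction.
#' @param rng_seed Integer seed governing all stochastic analysis steps
#'   (miss-duration matching, shuffles).
#' @return An object of class `hetpop_config`.
#' @export
analysis_config <- function(zscore_scope = c("global", "per_contrast"),
                            rt_exclusion_s = 0.150,
                            baseline_window_s = 30,
                            prestim_window_s = 3.0,
                            shuffle_iterations = list(hitmod = 1000L,
                                                      consistency = 100L,
                                                      similarity = 1000L),
                            fdr_alpha = 0.05,
                            rng_seed = 1L) {
  zscore_scope <- match.arg(zscore_scope)
  stopifnot(rt_exclusion_s >= 0, baseline_window_s > 0, prestim_window_s > 0,
            fdr_alpha > 0, fdr_alpha < 1)
  structure(list(zscore_scope = zscore_scope,
                 rt_exclusion_s = rt_exclusion_s,
                 baseline_window_s = baseline_window_s,
                 prestim_window_s = prestim_window_s,
                 shuffle_iterations = shuffle_iterations,
                 fdr_alpha = fdr_alpha,
                 rng_seed = as.integer(rng_seed)),
            class = "hetpop_config")
}

#' Construct a session object
#'
#' A session holds the raw somatic fluorescence (neurons x frames), optional
#' matched neuropil fluorescence, the frame rate, and a trial table. Frame
#' indices are 0-based with half-open intervals `[onset, offset)`.
#'
#' @param frame_rate Imaging frame rate in Hz.
#' @param soma Numeric matrix `[n_neurons x n_frames]` of somatic
#'   fluorescence (arbitrary units).
#' @param trials Data frame with columns `trial_index`, `direction_deg`,
#'   `contrast_pct`, `onset_frame`, `offset_frame`, `outcome`,
#'   `reaction_time_s` (NA when absent) and `block_index`.
#' @param neuropil Optional neuropil matrix, same shape as `soma`.
#' @return An object of class `hetpop_session`.
#' @export
session_data <- function(frame_rate, soma, trials, neuropil = NULL) {
  s <- structure(list(frame_rate = frame_rate,
                      soma = soma,
                      neuropil = neuropil,
                      trials = as.data.frame(trials)),
                 class = "hetpop_session")
  validate_session(s)
  s
}

required_trial_cols <- c("trial_index", "direction_deg", "contrast_pct",
                         "onset_frame", "offset_frame", "outcome",
                         "reaction_time_s", "block_index")

outcome_levels <- c("hit", "miss", "false_alarm", "correct_rejection")

#' Validate a session object
#'
#' Checks the trial-table schema, frame bounds, outcome/contrast
#' compatibility and reaction-time constraints. Errors name the offending
#' trial or field.
#'
#' @param session A `hetpop_session`.
#' @return The session, invisibly, if valid.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "hetpop_session"))
  if (!is.matrix(session$soma) || nrow(session$soma) < 2) {
    stop("soma fluorescence must be a matrix with at least 2 neurons")
  }
  if (!is.numeric(session$frame_rate) || session$frame_rate <= 0) {
    stop("frame_rate must be positive")
  }
  if (!is.null(session$neuropil) &&
      !identical(dim(session$neuropil), dim(session$soma))) {
    stop("neuropil matrix shape does not match soma matrix")
  }
  tr <- session$trials
  missing_cols <- setdiff(required_trial_cols, names(tr))
  if (length(missing_cols) > 0) {
    stop("trial table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tr) == 0) return(invisible(session))
  n_frames <- ncol(session$soma)
  bad <- which(!(tr$onset_frame < tr$offset_frame))
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]], ": onset_frame must be < offset_frame")
  }
  bad <- which(tr$offset_frame > n_frames | tr$onset_frame < 0)
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]], ": frame interval [",
         tr$onset_frame[bad[1]], ", ", tr$offset_frame[bad[1]],
         ") out of range for ", n_frames, " frames")
  }
  bad <- which(!(tr$outcome %in% outcome_levels))
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]], ": unknown outcome '",
         tr$outcome[bad[1]], "'")
  }
  # probe trials (0% contrast) are scored false_alarm/correct_rejection;
  # stimulus trials are scored hit/miss
  probe <- tr$contrast_pct == 0
  bad <- which(probe & tr$outcome %in% c("hit", "miss"))
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]], ": 0% contrast trial scored as ",
         tr$outcome[bad[1]])
  }
  bad <- which(!probe & tr$outcome %in% c("false_alarm", "correct_rejection"))
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]], ": nonzero contrast trial scored as ",
         tr$outcome[bad[1]])
  }
  responded <- tr$outcome %in% c("hit", "false_alarm")
  bad <- which(responded & !is.finite(tr$reaction_time_s))
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]], ": response trial lacks a reaction time")
  }
  bad <- which(is.finite(tr$reaction_time_s) & tr$reaction_time_s > 3.0)
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]], ": reaction time exceeds 3.0 s")
  }
  invisible(session)
}

#' Number of neurons / frames / trials in a session
#' @param session A `hetpop_session`.
#' @return Integer count.
#' @export
n_neurons <- function(session) nrow(session$soma)

#' @rdname n_neurons
#' @export
n_frames <- function(session) ncol(session$soma)

#' @rdname n_neurons
#' @export
n_trials <- function(session) nrow(session$trials)

#' @export
print.hetpop_session <- function(x, ...) {
  cat("<hetpop_session> ", n_neurons(x), " neurons x ", n_frames(x),
      " frames @ ", x$frame_rate, " Hz, ", n_trials(x), " trials",
      if (!is.null(x$neuropil)) " (+neuropil)", "\n", sep = "")
  invisible(x)
}

#' Read a session from a directory of delimited text files
#'
#' Expects `trials.tsv` (tab-separated, one header line) and
#' `soma_fluorescence.tsv` (neurons x frames, no header); optionally
#' `neuropil_fluorescence.tsv` and `frame_rate.txt` holding the rate in Hz.
#'
#' @param path Directory containing the session files.
#' @return A validated `hetpop_session`.
#' @seealso [write_session()]
#' @export
read_session <- function(path) {
  trial_file <- file.path(path, "trials.tsv")
  soma_file <- file.path(path, "soma_fluorescence.tsv")
  rate_file <- file.path(path, "frame_rate.txt")
  for (f in c(trial_file, soma_file, rate_file)) {
    if (!file.exists(f)) stop("missing session file: ", f)
  }
  trials <- read.delim(trial_file, sep = "\t", stringsAsFactors = FALSE)
  read_matrix <- function(file) {
    # scan() is far faster than read.delim for wide numeric matrices
    n_cols <- length(strsplit(readLines(file, n = 1), "\t", fixed = TRUE)[[1]])
    vals <- scan(file, what = numeric(), sep = "\t", quiet = TRUE)
    matrix(vals, ncol = n_cols, byrow = TRUE)
  }
  soma <- read_matrix(soma_file)
  neuropil <- NULL
  np_file <- file.path(path, "neuropil_fluorescence.tsv")
  if (file.exists(np_file)) neuropil <- read_matrix(np_file)
  frame_rate <- as.numeric(readLines(rate_file, n = 1))
  session_data(frame_rate, soma, trials, neuropil)
}

#' Write a session to a directory of delimited text files
#'
#' @param session A `hetpop_session`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.table(session$trials, file.path(path, "trials.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(session$soma, file.path(path, "soma_fluorescence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(session$neuropil)) {
    write.table(session$neuropil, file.path(path, "neuropil_fluorescence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  writeLines(format(session$frame_rate, digits = 17),
             file.path(path, "frame_rate.txt"))
  invisible(path)
}

#' Per-block condition-count report
#'
#' The task presents each of the 48 conditions (8 directions x 6 contrasts)
#' once per repetition block, in randomised order; 0%-contrast probes are
#' thus 8 of 48 trials (1:5 probe:stimulus). Reports per-block trial counts
#' and flags blocks deviating from that design. Report-only: never errors.
#'
#' @param session A `hetpop_session`.
#' @return Data frame with one row per block: `block_index`, `n_trials`,
#'   `n_probe`, `complete` (each condition exactly once).
#' @export
validate_blocks <- function(session) {
  tr <- session$trials
  if (nrow(tr) == 0) {
    return(data.frame(block_index = integer(0), n_trials = integer(0),
                      n_probe = integer(0), complete = logical(0)))
  }
  blocks <- sort(unique(tr$block_index))
  out <- lapply(blocks, function(b) {
    bt <- tr[tr$block_index == b, ]
    key <- paste(bt$direction_deg, bt$contrast_pct)
    full <- as.vector(outer(task_directions(), task_contrasts(), paste))
    complete <- nrow(bt) == 48 && setequal(key, full) && !anyDuplicated(key)
    data.frame(block_index = b, n_trials = nrow(bt),
               n_probe = sum(bt$contrast_pct == 0), complete = complete)
  })
  do.call(rbind, out)
}

#' Read an analysis configuration from a YAML file
#'
#' The file holds top-level keys matching the arguments of
#' [analysis_config()] (e.g. `zscore_scope`, `rt_exclusion_s`,
#' `shuffle_iterations` as a mapping); missing keys take the defaults.
#'
#' @param path Path to a YAML file.
#' @return An [analysis_config()] object.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, raw)
}
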