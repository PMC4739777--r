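#' Pairwise Euclidean distances within a labelled point set
#'
#' Each trial's population response is a point in n-dimensional neural
#' space; this computes all unique-pair Euclidean distances among the
#' points carrying one label (e.g. all hit trials) and summarises the
#' distribution by its mean.
#'
#' @param points Matrix `[n_points x n_dims]`.
#' @param labels Optional label per point; with `label`, restricts to one
#'   group.
#' @param label Label selecting the group (ignored if `labels` is NULL).
#' @return List: `distances` (vector over unique pairs), `mean_distance`.
#' @export
pairwise_distances <- function(points, labels = NULL, label = NULL) {
  if (!is.null(labels) && !is.null(label)) {
    points <- points[labels == label, , drop = FALSE]
  }
  stopifnot(nrow(points) >= 2)
  d <- as.numeric(dist(points))
  list(distances = d, mean_distance = mean(d))
}

#' Mirror a population response across the main diagonal
#'
#' Reflects a point through its projection on the all-equal diagonal by
#' inverting each neuron's deviation from the population mean:
#' `r' = mu_r - (r - mu_r) = 2 mu_r - r`. Mirroring preserves the
#' population mean and the distance to the diagonal, and is an involution.
#'
#' @param r Numeric population-response vector (length >= 2), or a matrix
#'   `[n_points x n_dims]` mirrored row-wise.
#' @return Mirrored vector or matrix.
#' @export
mirror_across_diagonal <- function(r) {
  if (is.matrix(r)) {
    stopifnot(ncol(r) >= 2)
    return(2 * rowMeans(r) - r)
  }
  stopifnot(length(r) >= 2)
  2 * mean(r) - r
}

#' Response-space asymmetry probed by one-at-a-time mirroring
#'
#' Mirrors each point across the diagonal one at a time, recomputes the
#' mean pairwise inter-point distance of the modified set, and reports the
#' mean change relative to the original set. A point cloud symmetric about
#' the diagonal yields ~0; a cloud concentrated on one side yields a
#' positive index.
#'
#' @param points Matrix `[n_points x n_dims]` (>= 3 points).
#' @return List: `asymmetry` (mean distance increase), `per_point`.
#' @export
mirroring_asymmetry <- function(points) {
  stopifnot(nrow(points) >= 3)
  base <- mean(dist(points))
  per <- vapply(seq_len(nrow(points)), function(i) {
    p <- points
    p[i, ] <- mirror_across_diagonal(p[i, ])
    mean(dist(p)) - base
  }, numeric(1))
  list(asymmetry = mean(per), per_point = per)
}

#' Remove the population mean from each trial's response vector
#'
#' Subtracts each trial's own population mean from its entries, leaving
#' the distance to the diagonal (multidimensional heterogeneity)
#' unchanged.
#'
#' @param points Matrix `[n_trials x n_neurons]`.
#' @return Matrix of the same shape with zero per-trial mean.
#' @export
remove_mean <- function(points) {
  stopifnot(ncol(points) >= 2)
  points - rowMeans(points)
}

#' Remove heterogeneity (normalise distance to the diagonal) per trial
#'
#' Two steps per trial: the response vector is divided by its
#' heterogeneity (the Euclidean norm of the deviations from the population
#' mean), then the mean change this causes is undone by adding back the
#' difference between old and new means. Afterwards every trial lies on a
#' cylinder of radius 1.0 around the main diagonal: its direction relative
#' to the diagonal is preserved, its distance is exactly 1, and its
#' population mean is unchanged. Trials exactly on the diagonal have
#' undefined direction and are dropped with a warning.
#'
#' @param points Matrix `[n_trials x n_neurons]`.
#' @return Matrix of transformed rows; attribute `dropped` lists removed
#'   row indices.
#' @export
remove_heterogeneity <- function(points) {
  stopifnot(ncol(points) >= 2)
  mu <- rowMeans(points)
  het <- sqrt(rowSums((points - mu)^2))
  bad <- which(het == 0)
  if (length(bad) > 0) {
    warning("dropping trial(s) exactly on the diagonal: ",
            paste(bad, collapse = ", "))
    points <- points[-bad, , drop = FALSE]
    mu <- mu[-bad]; het <- het[-bad]
  }
  scaled <- points / het
  out <- scaled + (mu - rowMeans(scaled))
  attr(out, "dropped") <- bad
  out
}

#' Remove both mean and heterogeneity
#'
#' Composition of [remove_heterogeneity()] and [remove_mean()]: every
#' remaining trial has zero population mean and unit deviation norm (the
#' response-space cylinder collapses onto a unit circle around the
#' origin).
#'
#' @inheritParams remove_heterogeneity
#' @return Transformed matrix; attribute `dropped` as in
#'   [remove_heterogeneity()].
#' @export
remove_both <- function(points) {
  h <- remove_heterogeneity(points)
  out <- remove_mean(h)
  attr(out, "dropped") <- attr(h, "dropped")
  out
}

#' Hit/miss decoding on original and transformed point clouds
#'
#' Leave-one-out diagonal-covariance Gaussian naive-Bayes decoding (class
#' means and SDs per neuron, see [loo_gaussian_nb()]) of the behavioural
#' response (hit vs miss) from the population point cloud,
#' applied to the original points and to the mean-removed,
#' heterogeneity-removed and both-removed variants. Balanced accuracy
#' (mean of per-class accuracies) is reported; chance is 0.5.
#'
#' @param points Matrix `[n_trials x n_neurons]` (raw dF/F responses).
#' @param labels Character per trial, `hit` or `miss`.
#' @param variants Which transforms to evaluate.
#' @return Data frame: `variant`, `balanced_accuracy`, `n_hit`, `n_miss`.
#' @export
hitmiss_decode_after_removal <- function(points, labels,
                                         variants = c("original", "mean_removed",
                                                      "het_removed", "both_removed")) {
  stopifnot(nrow(points) == length(labels),
            sum(labels == "hit") >= 2, sum(labels == "miss") >= 2)
  clouds <- list()
  if ("original" %in% variants) clouds$original <- list(p = points, l = labels)
  if ("mean_removed" %in% variants) {
    clouds$mean_removed <- list(p = remove_mean(points), l = labels)
  }
  if ("het_removed" %in% variants) {
    p <- remove_heterogeneity(points)
    l <- if (length(attr(p, "dropped")) > 0) labels[-attr(p, "dropped")] else labels
    clouds$het_removed <- list(p = p, l = l)
  }
  if ("both_removed" %in% variants) {
    p <- remove_both(points)
    l <- if (length(attr(p, "dropped")) > 0) labels[-attr(p, "dropped")] else labels
    clouds$both_removed <- list(p = p, l = l)
  }
  rows <- lapply(names(clouds), function(v) {
    cl <- clouds[[v]]
    fit <- loo_gaussian_nb(t(cl$p), cl$l)
    acc_hit <- mean(fit$correct[cl$l == "hit"], na.rm = TRUE)
    acc_miss <- mean(fit$correct[cl$l == "miss"], na.rm = TRUE)
    data.frame(variant = v, balanced_accuracy = mean(c(acc_hit, acc_miss)),
               n_hit = sum(cl$l == "hit"), n_miss = sum(cl$l == "miss"))
  })
  do.call(rbind, rows)
}
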