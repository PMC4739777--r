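# RNG scoping: analyses that draw random numbers (miss-duration matching,
# shuffle nulls) derive a sub-stream from the config seed and restore the
# caller's RNG state afterwards, so stages are reproducible in isolation.
local_rng <- function(seed, stream = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed((as.integer(seed) * 1000L + as.integer(stream)) %% 2147483647L)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# mean absolute pairwise difference of a vector in O(n log n):
# with sorted x, sum_{i<j} (x_j - x_i) = sum_j (2j - 1 - n) x_(j)
mean_abs_pairwise_diff <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 values")
  xs <- sort(x)
  s <- sum((2 * seq_len(n) - 1 - n) * xs)
  s / (n * (n - 1) / 2)
}

# extract the values matrix from hetpop_zscores / hetpop_responses / matrix
values_matrix <- function(x) {
  if (inherits(x, c("hetpop_zscores", "hetpop_responses"))) x$values else x
}
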