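#' Derive a child seed from a root seed and a stream label
#'
#' All randomized stages of the simulator (population synthesis, waiting-list
#' bootstrap, the daily chain) draw from their own child stream derived from a
#' single root seed. The derivation is a small deterministic hash of the stage
#' label folded into the root seed, kept inside the 32-bit integer range, so a
#' run is reproducible from the root seed alone and stages can be re-executed
#' in isolation.
#'
#' @param seed integer root seed.
#' @param label character stream label, e.g. `"population"`.
#' @return an integer seed suitable for [set.seed()].
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 131 + cc) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629 + 1)
}

#' Lower weighted median
#'
#' Smallest value `x` such that the cumulative normalized weight of
#' observations `<= x` reaches 0.5.
#'
#' @param x numeric values.
#' @param w nonnegative weights, same length as `x`.
#' @return the lower weighted median of `x`.
#' @export
weighted_median_lower <- function(x, w) {
  stopifnot(length(x) == length(w), length(x) >= 1L, all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  x[which(cumsum(w) >= 0.5 - 1e-12)[1L]]
}

# internal: validate that a named numeric distribution sums to 1
.check_distribution <- function(p, what, tol = 1e-9) {
  if (any(p < 0)) stop(sprintf("distribution '%s' has negative mass", what))
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("distribution '%s' sums to %.12f, not 1", what, sum(p)))
  invisible(p)
}

# internal: sample category indices from a named probability vector
.sample_cat <- function(n, probs) {
  sample.int(length(probs), n, replace = TRUE, prob = probs)
}
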