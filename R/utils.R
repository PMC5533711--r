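`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @keywords internal
geometric_mean <- function(x) {
  .assert(all(x > 0), "geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# Midrank (ties get the average of the tied positions), rank 1 = largest value.
.rank_desc <- function(x) rank(-x, ties.method = "average")

# Derive a 32-bit-safe RNG seed from a base seed and stream indices.
.derive_seed <- function(base, i = 0L, j = 0L) {
  as.integer((as.numeric(base) + 7919 * i + 104729 * j) %% 2147483647)
}
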