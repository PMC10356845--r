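#' @importFrom stats rnorm rbinom runif rbeta median cor sd aov pnorm qnorm
#'   pchisq as.formula complete.cases setNames t.test logLik plogis quantile
#' @importFrom utils head
NULL

# Internal assertion helper: stop with a caller-friendly message.
abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

# Derive a bounded child seed from a master seed and a stage offset.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1009) %% 2147483647)
}

# Run code under a temporary RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Row-wise Pearson correlation between aligned rows of two matrices.
row_correlations <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  sa <- sqrt(rowSums(a^2))
  sb <- sqrt(rowSums(b^2))
  rowSums(a * b) / (sa * sb)
}

# Proportion-based permutation p-value. `direction = "ge"` counts null >= obs.
proportion_p <- function(observed, null_values, direction = c("ge", "le"),
                         conservative = FALSE) {
  direction <- match.arg(direction)
  hits <- if (direction == "ge") sum(null_values >= observed)
          else sum(null_values <= observed)
  if (conservative) (hits + 1) / (length(null_values) + 1)
  else hits / length(null_values)
}

new_permutation_result <- function(observed_stat, null_values, direction,
                                   n_perm, seed, conservative = FALSE) {
  structure(
    list(
      observed_stat = observed_stat,
      null_values = null_values,
      p_value = proportion_p(observed_stat, null_values, direction,
                             conservative),
      direction = direction,
      n_perm = n_perm,
      seed = seed
    ),
    class = "reinstatr_perm"
  )
}

#' @export
print.reinstatr_perm <- function(x, ...) {
  cat("Permutation test (", x$n_perm, " permutations)\n", sep = "")
  cat("  observed statistic:", format(x$observed_stat, digits = 4), "\n")
  cat("  null mean:", format(mean(x$null_values), digits = 4),
      " sd:", format(sd(x$null_values), digits = 4), "\n")
  cat("  p (proportion ", x$direction, " observed): ",
      format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
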