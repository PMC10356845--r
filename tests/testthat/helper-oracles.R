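# Independent oracles used across tests; deliberately written from first
# principles, not via the package's own code paths.

# Midrank by counting: rank_i = #(x < x_i) + (1 + #(x == x_i)) / 2
oracle_midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2, numeric(1))
}

# Pearson correlation from the covariance / sd product formula
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum((a - sum(a) / n) * (b - sum(b) / n))
  den <- sqrt(sum((a - sum(a) / n)^2)) * sqrt(sum((b - sum(b) / n)^2))
  num / den
}

# All permutations of 1..n by recursive construction
oracle_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- oracle_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
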