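# Independent brute-force oracles used across test files.

# Sum over all length-l walks i -> j of the product of edge weights,
# enumerated recursively (exponential; only for tiny graphs).
walk_weight_oracle <- function(A, i, j, l) {
  n <- nrow(A)
  if (l == 1L) return(A[i, j])
  sum(vapply(seq_len(n), function(k) {
    if (A[i, k] == 0) 0 else A[i, k] * walk_weight_oracle(A, k, j, l - 1L)
  }, numeric(1L)))
}

# Benjamini-Hochberg by exhaustive search over all rejection thresholds:
# the largest rejection set {p <= t} (t a candidate p-value) that keeps
# the step-up inequality satisfied.
bh_brute_force <- function(p, q) {
  m <- length(p)
  best <- rep(FALSE, m)
  for (t in sort(unique(p))) {
    k <- sum(p <= t)
    if (t <= k * q / m && k > sum(best)) best <- p <= t
  }
  best
}

# Random symmetric non-negative weight matrix with zero diagonal.
random_pos_matrix <- function(n, density = 0.7) {
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  w <- stats::runif(sum(ut))
  w[stats::runif(sum(ut)) > density] <- 0
  A[ut] <- w
  A <- A + t(A)
  A
}

# Deterministic two-sinusoid series for correlation edge cases.
two_node_sinusoids <- function(T = 30, phase = pi) {
  t <- seq_len(T)
  bold_ts(rbind(sin(2 * pi * t / 10), sin(2 * pi * t / 10 + phase)),
          tr_seconds = 1)
}
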