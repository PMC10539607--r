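# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (loops, explicit combinatorics) and never share code
# with the implementation they check.

# Triple-loop topological overlap.
tom_oracle <- function(A) {
  n <- nrow(A)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, -i])
    kj <- sum(A[j, -j])
    out[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  dimnames(out) <- dimnames(A)
  out
}

# Exhaustive hypergeometric upper tail P(X >= a) from binomial coefficients.
hyper_tail_oracle <- function(a, size_a, size_b, n_universe) {
  ks <- a:min(size_a, size_b)
  sum(choose(size_a, ks) * choose(n_universe - size_a, size_b - ks)) /
    choose(n_universe, size_b)
}

# KS D by direct grid evaluation over every pooled point.
ks_grid_oracle <- function(x, y) {
  d <- 0
  for (t in c(x, y)) {
    d <- max(d, abs(sum(x <= t) / length(x) - sum(y <= t) / length(y)))
  }
  d
}

# Benjamini-Hochberg step-up by the defining formula.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[ord[i]] <- min(p[ord[js]] * m / js, 1)
  }
  q
}

# Spearman rho from average ranks.
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Small planted cohort used by several unit tests (2 modules x 30 genes,
# 60 background genes).
small_cohort <- function(seed = 1, noise_sd = 1) {
  simulate_cohort(n_genes = 120, n_samples = 80, n_modules = 2,
                  module_size = 30, noise_sd = noise_sd, seed = seed)
}

# Map each detected (non-grey) module label to the planted label that
# contributes most of its genes.
match_modules <- function(detected, truth) {
  labs <- setdiff(unique(detected), "grey")
  out <- character(0)
  for (l in labs) {
    genes <- names(detected)[detected == l]
    out[l] <- names(sort(table(truth$module[genes]), decreasing = TRUE))[1L]
  }
  out
}
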