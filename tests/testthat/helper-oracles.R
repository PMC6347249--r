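# Shared fixtures and independent oracles for the suite.

# Random count matrix with Poisson entries (the generic non-negative fixture).
rand_count_matrix <- function(n, d, lambda = 5, seed = 1) {
  set.seed(seed)
  matrix(rpois(n * d, lambda), n, d)
}

# Random real matrix with a guaranteed-full numerical rank.
rand_real_matrix <- function(n, d, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d)
}

# Brute-force pair-counting ARI: iterate all pairs and count agreements,
# then apply the chance correction from the pair totals. Independent of
# the contingency-table implementation in the package.
ari_pair_oracle <- function(x, y) {
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  n_pairs <- n * (n - 1) / 2
  a <- sum(same_x & same_y)          # together in both
  sum_x <- sum(same_x)               # together in x
  sum_y <- sum(same_y)               # together in y
  expected <- sum_x * sum_y / n_pairs
  max_index <- (sum_x + sum_y) / 2
  if (max_index == expected) return(1)
  (a - expected) / (max_index - expected)
}

# Direct KL-based Jensen-Shannon distance (base-2), the definitional form.
js_oracle <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  sqrt((kl(p, m) + kl(q, m)) / 2)
}
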