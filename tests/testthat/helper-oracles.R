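# Independent oracles used across the suite. These deliberately use naive
# O(n^3)/O(n^2) enumeration or closed forms, never the package's own code
# paths.

# Triple-loop VUS with the partial-credit tie convention. Counts the three
# triple categories as integers so the final value is computed from exact
# dyadic arithmetic, comparable bit-for-bit with any exact estimator.
brute_vus <- function(x, y, z, partial = TRUE) {
  n_full <- n_half <- n_sixth <- 0L
  for (xi in x) for (yj in y) for (zk in z) {
    if (xi < yj && yj < zk) n_full <- n_full + 1L
    else if (xi == yj && yj == zk) n_sixth <- n_sixth + 1L
    else if ((xi == yj && yj < zk) || (xi < yj && yj == zk)) n_half <- n_half + 1L
  }
  total <- if (partial) n_full + 0.5 * n_half + n_sixth / 6 else n_full
  total / (length(x) * length(y) * length(z))
}

# Pair-counting Kendall tau-b (vectorized sign enumeration over all pairs)
brute_kendall <- function(x, y) {
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  s <- sum(sx[up] * sy[up])
  n0 <- as.numeric(sum(up))
  tx <- as.numeric(sum(sx[up] == 0))
  ty <- as.numeric(sum(sy[up] == 0))
  s / sqrt((n0 - tx) * (n0 - ty))
}

# Step-up Hochberg adjustment built from the definition
brute_hochberg <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin((m - seq_len(m) + 1) * p[o], 1)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# True VUS of three Gaussian classes by numerical integration of P(X<Y<Z)
true_vus_normal <- function(mu, sd = c(1, 1, 1)) {
  stats::integrate(function(t)
    stats::dnorm(t, mu[2], sd[2]) * stats::pnorm(t, mu[1], sd[1]) *
      stats::pnorm(t, mu[3], sd[3], lower.tail = FALSE),
    -Inf, Inf, rel.tol = 1e-10)$value
}

# random strictly increasing maps for rank-invariance properties
random_monotone_map <- function() {
  switch(sample.int(4L, 1L),
         function(v) exp(v / 3),
         function(v) atan(v) * 2 + 0.01 * v,
         function(v) v^3 + v,
         function(v) stats::qlogis(stats::pnorm(v / 2)))
}

make_triple <- function(n = c(12, 9, 11), mu = c(0, 0.7, 1.4), ties = FALSE) {
  x <- rnorm(n[1], mu[1]); y <- rnorm(n[2], mu[2]); z <- rnorm(n[3], mu[3])
  if (ties) {
    x <- round(x * 2) / 2; y <- round(y * 2) / 2; z <- round(z * 2) / 2
  }
  list(x = x, y = y, z = z)
}
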