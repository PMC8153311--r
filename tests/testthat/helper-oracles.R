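# Independent quadrature oracles: adaptive integration of the continuous
# functionals, never touching the package's grid code paths.

quad_neg_entropy <- function(density_fn) {
  stats::integrate(function(p) {
    v <- density_fn(p)
    out <- numeric(length(v))
    pos <- v > 0
    out[pos] <- v[pos] * log(v[pos])
    out
  }, 0, 1, rel.tol = 1e-10)$value
}

quad_expected_bernoulli_entropy <- function(density_fn) {
  stats::integrate(function(p) {
    h <- -p * log(p) - (1 - p) * log1p(-p)
    h[p == 0 | p == 1] <- 0
    density_fn(p) * h
  }, 0, 1, rel.tol = 1e-10)$value
}

# Brute-force filtered counts straight from the defining geometric sum.
brute_filtered_counts <- function(x, lambda) {
  N <- length(x)
  r <- 1 / (1 + lambda)
  n1 <- 0
  n0 <- 0
  for (k in 0:(N - 1)) {
    n1 <- n1 + r^(k + 1) * x[N - k]
    n0 <- n0 + r^(k + 1) * (1 - x[N - k])
  }
  c(n1, n0)
}

# Dense-grid argmax of the per-observation profile (oracle for the
# root-finding based maxima locations).
dense_argmax_phi <- function(f, lambda, K = 200001) {
  p <- (seq_len(K) - 0.5) / K
  lp <- f * log(p) + (1 - f) * log1p(-p) -
    lambda * (-p * log(p) - (1 - p) * log1p(-p))
  p[which.max(lp)]
}
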