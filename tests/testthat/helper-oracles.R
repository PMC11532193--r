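# Dense-matrix brute-force oracles, kept independent of the package internals.

oracle_hat_diag <- function(X, w) {
  W <- diag(w, nrow = length(w))
  diag(X %*% solve(t(X) %*% W %*% X) %*% t(X) %*% W)
}

oracle_hc3 <- function(X, w, e, h) {
  W <- diag(w, nrow = length(w))
  bread <- solve(t(X) %*% W %*% X)
  meat <- t(X) %*% diag((e / (1 - h))^2, nrow = length(e)) %*% X
  bread %*% meat %*% bread
}

# step-up BH computed literally from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# a small reproducible two-covariate Poisson dataset
small_pois_data <- function(n = 40, seed = 11) {
  set.seed(seed)
  x <- rep(0:1, each = n / 2)
  y <- rpois(n, exp(1.5 + 0.7 * x))
  list(y = y, X = cbind("(Intercept)" = 1, x = x), x = x)
}
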