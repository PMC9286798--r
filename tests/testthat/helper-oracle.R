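# Independent brute-force implementations used as oracles. These share no
# code with the package internals: plain loops, stats::cov, base solve.

oracle_shrink <- function(s, lambda) {
  nu <- sum(diag(s)) / nrow(s)
  (1 - lambda) * s + lambda * nu * diag(nrow(s))
}

oracle_cov <- function(m) {
  if (nrow(m) < 2) return(matrix(0, ncol(m), ncol(m)))
  stats::cov(m)
}

# full-data regularized Fisher weights (class code 0 vs 1)
oracle_fisher_w <- function(x, code, lambda) {
  m1 <- colMeans(x[code == 0, , drop = FALSE])
  m2 <- colMeans(x[code == 1, , drop = FALSE])
  sc <- (oracle_shrink(oracle_cov(x[code == 0, , drop = FALSE]), lambda) +
         oracle_shrink(oracle_cov(x[code == 1, , drop = FALSE]), lambda)) / 2
  tryCatch(solve(sc, m2 - m1),
           error = function(e) as.vector(MASS::ginv(sc) %*% (m2 - m1)))
}

# rank AUC with ties counted one half
oracle_auc <- function(y, code) {
  r <- rank(y)
  n1 <- sum(code == 0); n2 <- sum(code == 1)
  (sum(r[code == 1]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

# leave-one-out projections and Az, refitting every fold independently
oracle_loo <- function(x, code, lambda) {
  n <- nrow(x)
  y <- numeric(n)
  for (j in seq_len(n)) {
    w <- oracle_fisher_w(x[-j, , drop = FALSE], code[-j], lambda)
    y[j] <- sum(w * x[j, ])
  }
  list(y = y, az = oracle_auc(y, code))
}
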