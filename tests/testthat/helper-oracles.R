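# Independent reference implementations used as oracles.

# Naive double-loop ReliefF for binary labels: explicit per-instance
# distance computation and neighbour accumulation, no shared code with the
# package implementation (same documented row-order tie-break).
relieff_oracle <- function(x, y, k) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  p <- ncol(x)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- ifelse(hi - lo == 0, 1, hi - lo)
  xs <- x
  for (j in seq_len(p)) xs[, j] <- (x[, j] - lo[j]) / rng[j]
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (l in seq_len(n)) d[l] <- sqrt(sum((xs[i, ] - xs[l, ])^2))
    same <- setdiff(which(y == y[i]), i)
    other <- which(y != y[i])
    hits <- same[order(d[same], same)][seq_len(k)]
    misses <- other[order(d[other], other)][seq_len(k)]
    for (j in seq_len(p)) {
      w[j] <- w[j] + sum(abs(xs[i, j] - xs[misses, j])) -
        sum(abs(xs[i, j] - xs[hits, j]))
    }
  }
  w / (n * k)
}

# Random binary-labeled table for oracle comparisons.
random_table <- function(n_per_class, p, shift = 0.5) {
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p, shift), n_per_class))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c("NON-RISK", "RISK"), each = n_per_class))
}

# Random 3-D rotation matrix (QR with positive diagonal).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))))
}
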