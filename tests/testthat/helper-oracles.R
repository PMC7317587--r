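# independent oracles used across tests; deliberately naive implementations

# exhaustive all-pairs shortest paths by Floyd-Warshall relaxation
fw_distances <- function(d) {
  n <- nrow(d)
  D <- d
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

cpl_oracle <- function(w) {
  d <- 1 / w
  d[w == 0] <- Inf
  D <- fw_distances(d)
  n <- nrow(w)
  sum(D[row(D) != col(D)]) / (n * (n - 1))
}

# Benjamini-Hochberg step-up by the definition: ranked p times m/rank,
# then a running minimum walking down from the largest rank
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  cur <- Inf
  for (k in m:1) {
    cur <- min(cur, (m / k) * ps[k])
    adj[k] <- min(1, cur)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# band-limited unit-variance noise for coherence fixtures (independent of
# the package's generator internals)
bl_noise <- function(n, fs, low, high) {
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  s <- signal::filtfilt(bf, rnorm(n + 2 * fs))[(fs + 1):(fs + n)]
  s / sd(s)
}

# random complete weighted graph with weights in (lo, hi]
random_complete_graph <- function(n, lo = 0.05, hi = 1) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2, lo, hi)
  w + t(w)
}
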