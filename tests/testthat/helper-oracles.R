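# Independent brute-force oracles used to contract-test the production code.
# These deliberately use naive enumeration, not the package's algorithms.

# transitivity by enumerating all node triples
brute_transitivity <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(a)
  triangles <- 0
  triads <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k && a[i, j] && a[j, k]) {
      triads <- triads + 1 # ordered path i-j-k
      if (a[i, k]) triangles <- triangles + 1
    }
  }
  # ordered paths count each triad twice and each closed one 6 times, so
  # closed/ordered equals 3 * Ntriangles / Ntriads
  if (triads == 0) 0 else triangles / triads
}

# modularity by the raw double sum over all node pairs
brute_modularity <- function(g, blocks) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- rowSums(a)
  m2 <- sum(k) # 2M
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (blocks[i] == blocks[j]) q <- q + a[i, j] - k[i] * k[j] / m2
  }
  q / m2
}

# per-position cross match lengths via the transparent reference scan
brute_cross_lambdas <- function(a, b) {
  vapply(seq_along(a$words), function(t) {
    match_length(a$words, t, b$words[b$times < a$times[t]])
  }, 0L)
}

# largest Fano root by two-stage grid scan (independent of the bisection)
grid_predictability <- function(h, z, coarse = 10000L) {
  f <- function(p) {
    hb <- ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
    hb + (1 - p) * log2(z - 1)
  }
  lo <- 1 / z
  hi <- 1
  for (pass in 1:2) {
    grid <- seq(lo, hi, length.out = coarse)
    vals <- f(grid)
    # f decreases from log2(z) to 0 on [1/z, 1]; root brackets where it crosses h
    idx <- which(vals >= h)
    i <- if (length(idx) == 0) 1L else max(idx)
    lo <- grid[i]
    hi <- grid[min(i + 1L, coarse)]
  }
  (lo + hi) / 2
}

# small random graph for metric-oracle sweeps
random_small_graph <- function(n, p = 0.4) {
  g <- igraph::sample_gnp(n, p)
  if (igraph::ecount(g) == 0) g <- igraph::add_edges(g, c(1, 2))
  g
}

# random timestamped stream pair over a small alphabet; times interleaved
random_stream_pair <- function(max_len = 200, z = 10) {
  na <- sample.int(max_len, 1)
  nb <- sample.int(max_len, 1) + 1L # target needs >= 2 words
  times <- sort(sample.int(4L * (na + nb), na + nb))
  pick <- sort(sample.int(na + nb, na))
  list(a = list(words = sample.int(z, na, TRUE), times = times[pick]),
       b = list(words = sample.int(z, nb, TRUE), times = times[-pick]))
}
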