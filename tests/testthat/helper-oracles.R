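# Independent oracles used across the test suite.

# Brute-force Zi/Pi from an adjacency matrix and a membership vector,
# written with explicit loops, independent of the package's vectorized path.
bruteZiPi <- function(adj, mem) {
  n <- nrow(adj)
  kWithin <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj[i, j] && mem[j] == mem[i]) kWithin[i] <- kWithin[i] + 1
    }
  }
  zi <- numeric(n)
  for (m in unique(mem)) {
    idx <- which(mem == m)
    mu <- sum(kWithin[idx]) / length(idx)
    sdv <- if (length(idx) > 1)
      sqrt(sum((kWithin[idx] - mu)^2) / (length(idx) - 1)) else 0
    for (i in idx) zi[i] <- if (sdv == 0) 0 else (kWithin[i] - mu) / sdv
  }
  pi <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(adj[i, ])
    if (ki == 0) { pi[i] <- 0; next }
    s <- 0
    for (m in unique(mem)) {
      kis <- sum(adj[i, mem == m])
      s <- s + (kis / ki)^2
    }
    pi[i] <- 1 - s
  }
  list(zi = zi, pi = pi)
}

# All undirected simple graphs on n nodes as adjacency matrices.
enumerateGraphs <- function(n) {
  nEdges <- n * (n - 1) / 2
  lapply(seq_len(2^nEdges) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(nEdges)]
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- bits
    adj + t(adj)
  })
}

# igraph from an adjacency matrix with stable node names.
graphFromAdj <- function(adj) {
  dimnames(adj) <- list(sprintf("n%02d", seq_len(nrow(adj))),
                        sprintf("n%02d", seq_len(nrow(adj))))
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# One-treatment simulation config, convenient for Monte-Carlo checks.
singleTreatmentConfig <- function(treatment = "13CH4", nReplicates = 3,
                                  noiseCv = 0.02, seed = 1) {
  conc <- c(NoCH4 = 1.27, `13CH4` = 5.43, `13CH4_NO3` = 0.091)
  simulationConfig(seed = seed, nReplicates = nReplicates,
                   treatments = treatment, noiseCv = noiseCv,
                   nh4Conc = conc[treatment],
                   no3Conc = structure(NA_real_, names = treatment),
                   no2Conc = structure(NA_real_, names = treatment))
}
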