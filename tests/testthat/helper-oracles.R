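# Independent brute-force oracles used to validate the fast implementations.

# literal double-loop transcription of the sample-entropy definition:
# psi_m counts template pairs within tolerance under the Chebyshev distance
sampen_oracle <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        A <- A + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) < r) B <- B + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(B / A)
}

# all-pairs breadth-first search over an adjacency matrix
bfs_distances_oracle <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] == 1)
        new <- nb[d[s, nb] == Inf & nb != s]
        d[s, new] <- dist
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# exhaustive triangle / triplet counting clustering coefficient
graph_metrics_oracle <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  cc_nodes <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    closed <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] == 1) closed <- closed + 1
      }
    }
    closed / (k * (k - 1) / 2)
  }, 0)
  d <- bfs_distances_oracle(adj)
  off <- d[upper.tri(d)]
  finite <- is.finite(off)
  list(strength = mean(deg), cc = mean(cc_nodes),
       L = if (any(finite) && sum(adj) > 0) mean(off[finite]) else NA_real_)
}

# AUC by brute-force counting over all positive/negative pairs (ties = 1/2)
auc_oracle <- function(x, positive) {
  pos <- x[positive]
  neg <- x[!positive]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# random symmetric 0/1 adjacency with no self-loops
random_adjacency <- function(n, p = 0.35) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}
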