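# Independent oracles and small fixture builders used across test files.

# A minimal "serum panel" of m independent features.
toy_panel <- function(m, prefix = "f") {
  data.frame(feature_id = sprintf("%s%04d", prefix, seq_len(m)),
             modality = "serum_protein", cell_type = "none",
             signaling_param = "none", stimulus = "none",
             analyte = sprintf("a%04d", seq_len(m)), subset = "none",
             pathway = "none", stringsAsFactors = FALSE)
}

# Single-cohort case/control subject table.
toy_subjects <- function(n_case, n_control, cohort = "hcv", seed = 1) {
  generate_subjects(list(cohorts = stats::setNames(list(
    list(case = list(n = n_case, age = c(30, 70)),
         control = list(n = n_control, age = c(30, 70)))), cohort)),
    seed = seed)
}

# Brute-force normal-equations OLS.
bf_ols <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  unname(drop(solve(t(X1) %*% X1) %*% t(X1) %*% y))
}

# Brute-force upper-tail hypergeometric probability by support enumeration.
bf_hyper_upper <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- seq(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exhaustive shortest-path betweenness (fractional credit) and eccentricity
# for a small undirected graph given as an adjacency matrix.
bf_centralities <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  npaths <- matrix(0, n, n); diag(npaths) <- 1
  # BFS from each source counting shortest paths
  for (s in seq_len(n)) {
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (dist[s, w] == Inf && w != s) {
            dist[s, w] <- dist[s, v] + 1
            nxt <- union(nxt, w)
          }
          if (dist[s, w] == dist[s, v] + 1) {
            npaths[s, w] <- npaths[s, w] + npaths[s, v]
          }
        }
      }
      frontier <- nxt
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
      if (s == v || t == v || dist[s, t] == Inf) next
      if (dist[s, v] + dist[v, t] == dist[s, t]) {
        btw[v] <- btw[v] + npaths[s, v] * npaths[v, t] / npaths[s, t]
      }
    }
  }
  ecc <- sapply(seq_len(n), function(v) {
    d <- dist[v, ][is.finite(dist[v, ])]
    if (length(d) <= 1) 0 else max(d)
  })
  list(betweenness = btw, eccentricity = ecc)
}

# Random connected-ish undirected graph on n nodes as an adjacency matrix.
random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.numeric(stats::runif(length(up)) < p)
  adj + t(adj)
}

# Correlation-like symmetric matrix from an adjacency (edges at rho = 0.8).
adj_to_corr <- function(adj, rho = 0.8) {
  corr <- adj * rho
  diag(corr) <- 1
  rownames(corr) <- colnames(corr) <- paste0("n", seq_len(nrow(adj)))
  corr
}
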