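# Independent oracles used by property and acceptance tests. These are
# deliberately naive re-derivations (enumeration, brute force, dense algebra)
# kept separate from the package implementations they check.

# Brute-force mutual information from an explicit contingency table (bits).
mi_bruteforce <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  acc <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] == 0) next
    pxy <- tab[i, j] / n
    acc <- acc + pxy * log2(pxy / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
  }
  acc
}

# Naive double-loop cluster aggregation of a cell-cell signaling matrix.
cluster_signaling_bruteforce <- function(P, labels, K) {
  Pc <- matrix(0, K, K)
  for (u in seq_len(K)) for (v in seq_len(K)) {
    cu <- which(labels == u); cv <- which(labels == v)
    if (!length(cu) || !length(cv)) next
    s <- 0
    for (i in cu) for (j in cv) s <- s + P[i, j]
    Pc[u, v] <- s / (length(cu) * length(cv))
  }
  Pc
}

# Textbook Dijkstra over a dense non-negative cost matrix (0 = no edge).
# Returns the vector of distances from `src` to every node (Inf if unreachable).
dijkstra_bruteforce <- function(A, src) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[src] <- 0
  visited <- rep(FALSE, n)
  for (step in seq_len(n)) {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    visited[u] <- TRUE
    for (v in which(A[u, ] > 0)) {
      if (dist[u] + A[u, v] < dist[v]) dist[v] <- dist[u] + A[u, v]
    }
  }
  dist
}

# Normalized closeness recomputed from the brute-force Dijkstra distances.
closeness_bruteforce <- function(M, mode = "out") {
  A <- M; diag(A) <- 0
  K <- nrow(A)
  if (mode == "in") A <- t(A)
  vapply(seq_len(K), function(v) {
    d <- dijkstra_bruteforce(A, v)[-v]
    r <- sum(is.finite(d))
    if (r == 0 || sum(d[is.finite(d)]) == 0) return(0)
    (r / sum(d[is.finite(d)])) * (r / (K - 1))
  }, numeric(1))
}

# Stationary distribution of the explicitly built Google matrix.
pagerank_bruteforce <- function(M, damping = 0.85) {
  K <- nrow(M)
  out <- rowSums(M)
  P <- matrix(1 / K, K, K)
  nz <- out > 0
  P[nz, ] <- M[nz, , drop = FALSE] / out[nz]
  G <- damping * P + (1 - damping) / K
  e <- eigen(t(G))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# Exhaustive best-path search by recursive depth-first enumeration
# (independent of the pracma::perms-based implementation).
best_path_bruteforce <- function(W, start) {
  K <- nrow(W)
  best <- NULL
  best_score <- -Inf
  recurse <- function(path, remaining, score) {
    if (!length(remaining)) {
      if (score > best_score + 1e-12 ||
          (abs(score - best_score) <= 1e-12 &&
           (is.null(best) || paste(path, collapse = ",") <
              paste(best, collapse = ",")))) {
        best <<- path; best_score <<- score
      }
      return(invisible())
    }
    for (nxt in remaining) {
      recurse(c(path, nxt), setdiff(remaining, nxt),
              score + W[path[length(path)], nxt])
    }
  }
  recurse(start, setdiff(seq_len(K), start), 0)
  best
}
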