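#' Consensus cell-cell similarity from repeated PCA + k-means runs
#'
#' Captures cell-cell similarity by consensus clustering: cells are projected
#' onto the top `d` principal components and partitioned with k-means, over a
#' grid of `(k, d, run-seed)` settings; the similarity between two cells is
#' the fraction of runs in which they share a cluster. The diagonal is 1.
#'
#' @param X Cell x gene matrix of log-transformed expression (selected genes).
#' @param k_values Integer vector of cluster counts for the k-means runs.
#' @param d_values Integer vector of PCA dimensionalities (capped at
#'   `min(n - 1, p)`).
#' @param n_seeds Number of random restarts per `(k, d)` setting.
#' @param seed Master seed; the matrix is deterministic given it.
#' @return An `n x n` symmetric similarity matrix in `[0, 1]` with unit
#'   diagonal and cell ids as dimnames.
#' @export
consensus_similarity <- function(X, k_values = 3:8, d_values = c(4, 6, 8, 10),
                                 n_seeds = 10L, seed = 0L) {
  validate_expression(X)
  n <- nrow(X)
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 2)) abort("all `k_values` must be >= 2.")
  if (max(k_values) > n) abort("`k_values` cannot exceed the number of cells.")
  d_cap <- min(n - 1L, ncol(X))
  d_values <- sort(unique(pmin(as.integer(d_values), d_cap)))
  assert_count(n_seeds, "n_seeds")

  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = max(d_values))$x
  acc <- matrix(0, n, n)
  runs <- 0L
  with_local_seed(seed, {
    for (d in d_values) {
      Z <- pc[, seq_len(d), drop = FALSE]
      for (k in k_values) {
        for (s in seq_len(n_seeds)) {
          # k = n degenerates to every cell in its own cluster
          lab <- if (k == n) seq_len(n) else
            kmeans(Z, centers = k, iter.max = 100L, nstart = 1L)$cluster
          acc <- acc + outer(lab, lab, "==")
          runs <- runs + 1L
        }
      }
    }
  })
  S <- acc / runs
  diag(S) <- 1
  dimnames(S) <- list(rownames(X), rownames(X))
  S
}

validate_similarity <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) abort("`S` must be a square matrix.")
  if (max(abs(S - t(S))) > 1e-12) abort("`S` must be symmetric.")
  if (any(S < -1e-12) || any(S > 1 + 1e-12)) abort("`S` entries must lie in [0, 1].")
  invisible(S)
}

#' Choose the number of cell states by the Laplacian eigen-gap
#'
#' Computes the symmetric normalized graph Laplacian
#' `L = I - D^(-1/2) S D^(-1/2)` of the similarity matrix and returns the `k`
#' in `[k_min, k_max]` with the largest gap between consecutive sorted
#' eigenvalues `lambda_(k+1) - lambda_k`. The search starts at `k_min = 3`
#' because an EMT system has at least an E state, an M state and one
#' intermediate state. Ties resolve to the smallest `k`.
#'
#' @param S Symmetric similarity matrix in `[0, 1]`.
#' @param k_min,k_max Search range, `3 <= k_min <= k_max < n`.
#' @return The selected integer number of clusters.
#' @export
estimate_num_clusters <- function(S, k_min = 3L, k_max = 8L) {
  validate_similarity(S)
  n <- nrow(S)
  k_min <- assert_count(k_min, "k_min", min = 3L)
  k_max <- assert_count(k_max, "k_max", min = k_min)
  if (k_max >= n) abort("`k_max` must be smaller than the number of cells.")
  d <- rowSums(S)
  if (any(d <= 0)) abort("degenerate similarity: a row sums to zero.")
  inv_sqrt <- 1 / sqrt(d)
  L <- diag(n) - (inv_sqrt %o% inv_sqrt) * S
  lambda <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  ks <- k_min:k_max
  gaps <- lambda[ks + 1L] - lambda[ks]
  # ties (within numerical jitter of the largest gap) resolve to smallest k
  ks[which(gaps >= max(gaps) - 1e-10)[1]]
}

#' Soft cell-to-cluster assignment by symmetric NMF
#'
#' Factorizes the similarity matrix as `S ~ H H'` with `H >= 0` by damped
#' multiplicative updates `H <- H * (1 - beta + beta * (S H) / (H H' H))`
#' with `beta = 0.5`, initialized from the absolute top-`K` eigenvectors of
#' `S` plus a small seeded jitter. On return each row of `H` is normalized to
#' the probability simplex, giving the probability of each cell belonging to
#' each cluster.
#'
#' @param S Symmetric similarity matrix.
#' @param K Number of clusters (>= 2).
#' @param max_iter Maximum multiplicative updates.
#' @param tol Relative objective-decrease stopping tolerance.
#' @param seed Seed for the jitter.
#' @return An `n x K` matrix with rows on the simplex, with attributes
#'   `objective` (Frobenius objective trace, pre-normalization) and
#'   `converged` (logical; `FALSE` triggers a warning, not an error).
#' @export
soft_cluster <- function(S, K, max_iter = 2000L, tol = 1e-6, seed = 0L) {
  validate_similarity(S)
  K <- assert_count(K, "K", min = 2L)
  n <- nrow(S)
  if (K > n) abort("`K` cannot exceed the number of cells.")
  eig <- eigen(S, symmetric = TRUE)
  lam <- pmax(eig$values[seq_len(K)], 0)
  # scaled so that H H' approximates S at the start, otherwise the first
  # multiplicative step overshoots
  H <- abs(eig$vectors[, seq_len(K), drop = FALSE]) %*% diag(sqrt(lam), K)
  H <- with_local_seed(seed, H + matrix(runif(n * K, 0, 0.01), n, K))

  beta <- 0.5
  obj <- function(H) sum((S - tcrossprod(H))^2)
  trace <- numeric(0)
  prev <- obj(H)
  trace <- prev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    num <- S %*% H
    den <- H %*% crossprod(H)
    den[den < 1e-12] <- 1e-12
    H <- H * (1 - beta + beta * num / den)
    cur <- obj(H)
    trace <- c(trace, cur)
    if (abs(prev - cur) < tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!converged) warn("symmetric NMF did not converge within `max_iter` updates.")
  rs <- rowSums(H)
  rs[rs < 1e-12] <- 1e-12
  H <- H / rs
  dimnames(H) <- list(rownames(S), NULL)
  attr(H, "objective") <- trace
  attr(H, "converged") <- converged
  H
}

#' Cell plasticity index (CPI)
#'
#' Normalized entropy of each cell's cluster-membership probabilities:
#' `CPI_i = -sum_k H[i,k] log H[i,k] / log K`, with `0 log 0 = 0`. A one-hot
#' cell scores 0; a cell with uniform membership scores 1. Cells with high
#' CPI are candidates for transition cells.
#'
#' @param H Cell x cluster membership matrix with rows on the simplex.
#' @return Numeric vector in `[0, 1]`, named by cell id when available.
#' @export
compute_cpi <- function(H) {
  H <- membership_matrix(H)
  K <- ncol(H)
  P <- H
  P[P <= 0] <- 1 # contributes 0 to the entropy
  cpi <- -rowSums(H * log(P)) / log(K)
  pmin(pmax(cpi, 0), 1)
}

membership_matrix <- function(H) {
  if (inherits(H, "emt_cluster_model")) H <- H$H
  if (!is.matrix(H) || any(H < -1e-9)) abort("`H` must be a non-negative matrix.")
  if (ncol(H) < 2) abort("`H` must have at least two clusters.")
  if (any(abs(rowSums(H) - 1) > 1e-6)) abort("rows of `H` must sum to 1.")
  H
}

#' Bundle a soft assignment into a cluster model
#'
#' Attaches hard labels (`argmax` per row, ties to the smallest cluster
#' index) and the cell plasticity index to a soft membership matrix.
#'
#' @param H Cell x cluster membership matrix (e.g. from [soft_cluster()]).
#' @return An object of class `emt_cluster_model`: list with `H`, `labels`,
#'   `cpi`, `K`.
#' @export
cluster_model <- function(H) {
  Hm <- membership_matrix(H)
  structure(list(
    H = Hm,
    labels = max.col(Hm, ties.method = "first"),
    cpi = compute_cpi(Hm),
    K = ncol(Hm)
  ), class = "emt_cluster_model")
}

#' @export
print.emt_cluster_model <- function(x, ...) {
  cat(sprintf("<emt_cluster_model> %d cells, K = %d, mean CPI %.3f\n",
              nrow(x$H), x$K, mean(x$cpi)))
  invisible(x)
}
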