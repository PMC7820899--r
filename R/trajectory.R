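#' Identify transition cells from a cluster model
#'
#' Transition cells (TCs) are the cells with the highest plasticity: either
#' all cells with `CPI > cpi_threshold`, or the `ceiling(top_fraction * n)`
#' highest-CPI cells (ties broken by cell index). Each TC is annotated with
#' the unordered pair of its two largest cluster memberships (membership
#' ties resolve to the smaller cluster indices). Supply exactly one selector;
#' with neither, the default `top_fraction = 0.2` is used.
#'
#' @param model An [cluster_model()] object.
#' @param cpi_threshold CPI cut-off selector.
#' @param top_fraction Fraction-of-cells selector in `(0, 1]`.
#' @return A tibble of class `emt_tcs` with columns `cell`, `cell_id`, `cpi`,
#'   `cluster_a`, `cluster_b` (`cluster_a < cluster_b`), and attributes
#'   `params`, `n_total`, `K`.
#' @export
identify_transition_cells <- function(model, cpi_threshold = NULL,
                                      top_fraction = NULL) {
  stopifnot(inherits(model, "emt_cluster_model"))
  if (!is.null(cpi_threshold) && !is.null(top_fraction)) {
    abort("supply exactly one of `cpi_threshold` or `top_fraction`.")
  }
  if (is.null(cpi_threshold) && is.null(top_fraction)) top_fraction <- 0.2
  n <- nrow(model$H)
  cpi <- model$cpi
  if (!is.null(cpi_threshold)) {
    assert_fraction(cpi_threshold, "cpi_threshold", 0, 1)
    idx <- which(cpi > cpi_threshold)
    params <- list(mode = "threshold", value = cpi_threshold)
  } else {
    assert_fraction(top_fraction, "top_fraction", 0, 1, lo_open = TRUE)
    m <- ceiling(top_fraction * n)
    idx <- order(-cpi, seq_len(n))[seq_len(m)]
    idx <- sort(idx)
    params <- list(mode = "top_fraction", value = top_fraction)
  }
  pairs <- t(vapply(idx, function(i) {
    sort(order(-model$H[i, ], seq_len(model$K))[1:2])
  }, integer(2)))
  ids <- rownames(model$H) %||% as.character(seq_len(n))
  out <- tibble(
    cell = as.integer(idx),
    cell_id = ids[idx],
    cpi = unname(cpi[idx]),
    cluster_a = if (length(idx)) pairs[, 1] else integer(),
    cluster_b = if (length(idx)) pairs[, 2] else integer()
  )
  structure(out, class = c("emt_tcs", class(out)),
            params = params, n_total = n, K = model$K)
}

#' Cluster-cluster transition weights from transition cells
#'
#' `W[u, v]` is the fraction of all cells that are TCs between clusters `u`
#' and `v`, i.e. the percentage of TCs between two clusters relative to the
#' total cell count. Symmetric with zero diagonal.
#'
#' @param tcs An [identify_transition_cells()] result.
#' @param n_total Total number of cells (defaults to the value recorded in
#'   `tcs`).
#' @param K Number of clusters (defaults to the value recorded in `tcs`).
#' @return A `K x K` symmetric matrix of TC fractions.
#' @export
cluster_transition_weights <- function(tcs, n_total = attr(tcs, "n_total"),
                                       K = attr(tcs, "K")) {
  K <- assert_count(K, "K", min = 2L)
  n_total <- assert_count(n_total, "n_total", min = 0L)
  if (n_total < nrow(tcs)) abort("`n_total` must be at least the number of TCs.")
  W <- matrix(0, K, K)
  if (nrow(tcs) > 0) {
    for (i in seq_len(nrow(tcs))) {
      u <- tcs$cluster_a[i]; v <- tcs$cluster_b[i]
      W[u, v] <- W[u, v] + 1
      W[v, u] <- W[v, u] + 1
    }
    W <- W / n_total
  }
  W
}

#' Rank clusters as terminal-state (E/M) candidates
#'
#' Ranks clusters by total TC involvement (row sum of the transition-weight
#' matrix), ascending, ties by cluster index. Clusters with the fewest TCs
#' around them are the epithelial/mesenchymal terminal-state candidates; the
#' caller decides which end is epithelial using marker expression.
#'
#' @param W Transition-weight matrix from [cluster_transition_weights()].
#' @return Integer vector: all clusters ranked from least to most TC
#'   involvement.
#' @export
select_terminal_states <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), nrow(W) >= 2)
  involvement <- rowSums(W)
  order(involvement, seq_len(nrow(W)))
}

#' Infer the cluster transition trajectory
#'
#' Exhaustively searches all Hamiltonian paths over the clusters starting at
#' `start` and returns the one maximizing the sum of transition weights along
#' consecutive pairs. Ties resolve to the lexicographically smallest path.
#' Exhaustive search is enforced for `K <= 10`.
#'
#' @param W `K x K` transition-weight matrix.
#' @param start Starting cluster (1-based), typically a terminal-state
#'   candidate from [select_terminal_states()].
#' @return Integer vector: ordered cluster path of length `K` beginning at
#'   `start`.
#' @export
infer_trajectory <- function(W, start) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  K <- nrow(W)
  if (K > 10) abort("exhaustive trajectory search supports at most 10 clusters.")
  start <- assert_count(start, "start")
  if (start > K) abort("`start` is not a valid cluster index.")
  rest <- setdiff(seq_len(K), start)
  if (length(rest) == 0) return(start)
  if (length(rest) == 1) return(c(start, rest))
  perms <- pracma::perms(rest)
  paths <- cbind(start, perms)
  score <- vapply(seq_len(nrow(paths)), function(r) {
    p <- paths[r, ]
    sum(W[cbind(p[-K], p[-1])])
  }, numeric(1))
  best <- which(score >= max(score) - 1e-12)
  cand <- paths[best, , drop = FALSE]
  ord <- do.call(order, as.data.frame(cand))
  as.integer(cand[ord[1], ])
}

#' Pseudotime along a cluster trajectory
#'
#' Membership-weighted trajectory position: with `pos(c)` the 0-based index
#' of cluster `c` on the path, `pseudotime_i = sum_k pos(k) H[i,k] / (K-1)`.
#' A cell fully in the first path cluster scores 0; fully in the last, 1.
#'
#' @param H Cell x cluster membership matrix (or an `emt_cluster_model`).
#' @param path Ordered cluster path covering all `K` clusters.
#' @return Numeric vector in `[0, 1]`, named by cell id when available.
#' @export
compute_pseudotime <- function(H, path) {
  H <- membership_matrix(H)
  K <- ncol(H)
  if (length(path) != K || !setequal(path, seq_len(K))) {
    abort("`path` must be a permutation of 1..K.")
  }
  pos <- match(seq_len(K), path) - 1
  drop(H %*% pos) / (K - 1)
}

#' Marker-gene likelihoods per cluster by non-negative factorization
#'
#' For each gene, solves the non-negative least-squares problem
#' `x_g ~ H g` for the gene's per-cluster loading `g >= 0`, i.e. factorizes
#' the expression matrix as the product of cell-to-cluster probabilities and
#' per-cluster gene likelihoods. The marker score of gene `g` for cluster `k`
#' is the loading normalized across clusters (rows summing to 1; all-zero
#' loadings score 0 everywhere).
#'
#' @param X Cell x gene matrix (log-transformed expression).
#' @param H Cell x cluster membership matrix (or model).
#' @param top_m Markers reported per cluster (default 5, the usual "union of
#'   top five marker genes per cluster" rule).
#' @return An object of class `emt_marker_table`: list with `scores`
#'   (gene x K matrix of normalized likelihoods) and `top_markers` (tibble
#'   with `cluster`, `gene_id`, `score`, `rank`).
#' @export
infer_marker_genes <- function(X, H, top_m = 5L) {
  validate_expression(X)
  H <- membership_matrix(H)
  if (nrow(X) != nrow(H)) abort("`X` and `H` must describe the same cells.")
  top_m <- assert_count(top_m, "top_m")
  K <- ncol(H)
  G <- t(apply(X, 2, function(xg) pracma::lsqnonneg(H, xg)$x))
  rs <- rowSums(G)
  scores <- G / ifelse(rs > 0, rs, 1)
  scores[rs == 0, ] <- 0
  dimnames(scores) <- list(colnames(X), NULL)

  top <- purrr::map_dfr(seq_len(K), function(k) {
    ord <- order(-scores[, k], colnames(X))
    take <- head(ord, min(top_m, ncol(X)))
    tibble(cluster = k, gene_id = colnames(X)[take],
           score = scores[take, k], rank = seq_along(take))
  })
  structure(list(scores = scores, top_markers = top),
            class = "emt_marker_table")
}

#' @export
print.emt_marker_table <- function(x, ...) {
  cat(sprintf("<emt_marker_table> %d genes x %d clusters; top markers:\n",
              nrow(x$scores), ncol(x$scores)))
  print(x$top_markers, n = 10)
  invisible(x)
}

#' Transition genes between two adjacent clusters
#'
#' Restricts to the cells whose two largest memberships are exactly the given
#' cluster pair (which includes that pair's transition cells) and ranks genes
#' by the absolute Spearman correlation of expression with pseudotime.
#' Constant genes have undefined correlation and are scored 0 (ranked last).
#'
#' @param X Cell x gene matrix (log-transformed expression).
#' @param H Cell x cluster membership matrix (or model).
#' @param pseudotime Per-cell pseudotime from [compute_pseudotime()].
#' @param pair Integer vector of two distinct cluster indices, adjacent on
#'   the trajectory.
#' @param top_m Optional cap on the number of genes returned.
#' @return Tibble with `gene_id`, `rho` (signed Spearman correlation),
#'   `score` (`|rho|`), `rank`, sorted by decreasing score (ties by gene id).
#' @export
infer_transition_genes <- function(X, H, pseudotime, pair, top_m = NULL) {
  validate_expression(X)
  H <- membership_matrix(H)
  stopifnot(length(pseudotime) == nrow(X), nrow(H) == nrow(X))
  pair <- sort(as.integer(pair))
  if (length(pair) != 2 || pair[1] == pair[2]) abort("`pair` must be two distinct clusters.")
  top2 <- t(apply(H, 1, function(h) sort(order(-h, seq_along(h))[1:2])))
  in_pair <- top2[, 1] == pair[1] & top2[, 2] == pair[2]
  if (sum(in_pair) < 3) {
    abort(sprintf("fewer than 3 cells bridge clusters %d and %d.", pair[1], pair[2]))
  }
  Xs <- X[in_pair, , drop = FALSE]
  pt <- pseudotime[in_pair]
  rho <- suppressWarnings(apply(Xs, 2, function(g) cor(g, pt, method = "spearman")))
  rho[!is.finite(rho)] <- 0
  out <- tibble(gene_id = colnames(X), rho = unname(rho),
                score = abs(unname(rho))) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (!is.null(top_m)) out <- head(out, assert_count(top_m, "top_m"))
  out
}
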