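#' Inter-layer links from cell states to target genes
#'
#' The weight of the link from state `S_k` to target gene `t` is the mean
#' expression of `t` over the cells of state `k` (0 for an empty state).
#' The global top `ceiling(keep_fraction * K * |T|)` links by weight are
#' kept (ties broken by state then gene id); default `keep_fraction` 0.20.
#'
#' @param X Cell x gene matrix (log-transformed expression).
#' @param labels Per-cell cluster index in `1..K`.
#' @param targets Non-empty character vector of target gene ids.
#' @param K Number of states (default `max(labels)`).
#' @param keep_fraction Fraction of candidate links kept.
#' @return Tibble with `state`, `gene`, `weight`.
#' @export
target_expression_links <- function(X, labels, targets, K = max(labels),
                                    keep_fraction = 0.20) {
  validate_expression(X)
  if (length(targets) == 0) abort("`targets` must be non-empty.")
  assert_fraction(keep_fraction, "keep_fraction", 0, 1, lo_open = TRUE)
  K <- assert_count(K, "K")
  targets <- as.character(targets)
  missing <- setdiff(targets, colnames(X))
  if (length(missing)) {
    abort(sprintf("target gene(s) absent: %s", paste(missing, collapse = ", ")))
  }
  cand <- tidyr::expand_grid(state = seq_len(K), gene = targets) |>
    dplyr::mutate(weight = purrr::map2_dbl(.data$state, .data$gene, function(k, g) {
      cells <- labels == k
      if (!any(cells)) 0 else mean(X[cells, g])
    })) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$state, .data$gene)
  head(cand, ceiling(keep_fraction * K * length(targets)))
}

#' Inter-layer links from target genes to marker genes
#'
#' Per state, runs the PID confidence pipeline on the union of target and
#' marker genes restricted to that state's cells, retains only the
#' target-marker cross pairs, and keeps the global top
#' `ceiling(keep_fraction * K * |T| * |A|)` links by confidence; default
#' `keep_fraction` 0.015.
#'
#' @inheritParams target_expression_links
#' @param markers Character vector of marker gene ids.
#' @param n_bins Passed to [discretize_matrix()].
#' @return Tibble with `state`, `target`, `marker`, `weight`.
#' @export
target_marker_links <- function(X, labels, targets, markers, K = max(labels),
                                keep_fraction = 0.015, n_bins = NULL) {
  validate_expression(X)
  targets <- as.character(targets); markers <- as.character(markers)
  genes <- union(targets, markers)
  if (length(genes) < 3) abort("need at least 3 genes across targets and markers.")
  assert_fraction(keep_fraction, "keep_fraction", 0, 1, lo_open = TRUE)
  K <- assert_count(K, "K")
  cand <- purrr::map_dfr(seq_len(K), function(k) {
    cells <- which(labels == k)
    if (length(cells) < 5) {
      abort(sprintf("state %d has fewer than 5 cells for PID.", k))
    }
    Xs <- X[cells, genes, drop = FALSE]
    C <- confidence_network(puc_matrix(discretize_matrix(Xs, n_bins = n_bins)))
    tidyr::expand_grid(target = targets, marker = markers) |>
      dplyr::filter(.data$target != .data$marker) |>
      dplyr::mutate(state = k, weight = C[cbind(.data$target, .data$marker)])
  })
  cand <- dplyr::arrange(cand, dplyr::desc(.data$weight), .data$state,
                         .data$target, .data$marker) |>
    dplyr::select("state", "target", "marker", "weight")
  head(cand, ceiling(keep_fraction * K * length(targets) * length(markers)))
}

#' Assemble the hierarchical multilayer EMT network
#'
#' Builds the multilayer network `M = (V_M, E_M, V, L)` with two aspects: the
#' hierarchy aspect (layer 1 cell-cell communication, layer 2 target-gene
#' GRNs, layer 3 marker-gene GRNs) and the cell-state aspect (one elementary
#' layer per state, ordered along the trajectory). Layer-1 intra edges are
#' the directed cluster-cluster signaling probabilities above
#' `signaling_threshold`; layer-2/3 intra edges come from the per-state
#' GRNs; inter-layer edges link states to their expressed targets (1 -> 2)
#' and targets to markers (2 -> 3).
#'
#' @param Pc An [cluster_signaling()] result, or a `K x K` matrix.
#' @param target_grns,marker_grns Lists (one [state_grn()] per state).
#' @param expr_links [target_expression_links()] result.
#' @param cross_links [target_marker_links()] result.
#' @param signaling_threshold Layer-1 edge threshold; default 0.5 (0.7 is the
#'   stricter alternative also in use for this construction).
#' @param state_order Trajectory order of the state layers (default `1..K`).
#' @return An object of class `emt_multilayer`: list with `nodes` (tibble:
#'   `id`, `hierarchy_layer`, `state_layer`), `edges` (tibble: `src`,
#'   `src_layer`, `src_state`, `dst`, `dst_layer`, `dst_state`, `weight`,
#'   `kind`), `states`, `targets`, `markers`, `state_order`,
#'   `signaling_threshold`.
#' @export
assemble_multilayer <- function(Pc, target_grns, marker_grns, expr_links,
                                cross_links, signaling_threshold = 0.5,
                                state_order = NULL) {
  M <- if (inherits(Pc, "emt_cluster_signaling")) Pc$Pc else Pc
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  K <- nrow(M)
  assert_fraction(signaling_threshold, "signaling_threshold", 0, 1)
  state_order <- if (is.null(state_order)) seq_len(K) else as.integer(state_order)
  if (!setequal(state_order, seq_len(K))) abort("`state_order` must permute 1..K.")
  if (length(target_grns) != K || length(marker_grns) != K) {
    abort("need one target GRN and one marker GRN per state.")
  }
  targets <- sort(unique(unlist(lapply(target_grns, attr, "genes"))))
  markers <- sort(unique(unlist(lapply(marker_grns, attr, "genes"))))

  nodes <- dplyr::bind_rows(
    tibble(id = sprintf("S%d", seq_len(K)), hierarchy_layer = 1L,
           state_layer = seq_len(K)),
    tidyr::expand_grid(state_layer = seq_len(K), id = targets) |>
      dplyr::mutate(hierarchy_layer = 2L),
    tidyr::expand_grid(state_layer = seq_len(K), id = markers) |>
      dplyr::mutate(hierarchy_layer = 3L)
  ) |> dplyr::select("id", "hierarchy_layer", "state_layer")

  edge_row <- function(src, sl, ss, dst, dl, ds, w, kind) {
    tibble(src = src, src_layer = sl, src_state = ss,
           dst = dst, dst_layer = dl, dst_state = ds,
           weight = w, kind = kind)
  }
  idx <- which(M > signaling_threshold, arr.ind = TRUE)
  e1 <- edge_row(sprintf("S%d", idx[, 1]), 1L, as.integer(idx[, 1]),
                 sprintf("S%d", idx[, 2]), 1L, as.integer(idx[, 2]),
                 M[idx], "intra1")
  e2 <- purrr::map_dfr(seq_len(K), function(k) {
    g <- target_grns[[k]]
    if (nrow(g) == 0) return(NULL)
    edge_row(g$gene_x, 2L, k, g$gene_y, 2L, k, g$weight, "intra2")
  })
  e3 <- purrr::map_dfr(seq_len(K), function(k) {
    g <- marker_grns[[k]]
    if (nrow(g) == 0) return(NULL)
    edge_row(g$gene_x, 3L, k, g$gene_y, 3L, k, g$weight, "intra3")
  })
  e12 <- edge_row(sprintf("S%d", expr_links$state), 1L, expr_links$state,
                  expr_links$gene, 2L, expr_links$state,
                  expr_links$weight, "inter12")
  e23 <- edge_row(cross_links$target, 2L, cross_links$state,
                  cross_links$marker, 3L, cross_links$state,
                  cross_links$weight, "inter23")
  edges <- dplyr::bind_rows(e1, e2, e3, e12, e23)

  key <- function(id, layer, state) paste(id, layer, state, sep = "@")
  node_keys <- key(nodes$id, nodes$hierarchy_layer, nodes$state_layer)
  bad <- !(key(edges$src, edges$src_layer, edges$src_state) %in% node_keys) |
    !(key(edges$dst, edges$dst_layer, edges$dst_state) %in% node_keys)
  if (any(bad)) {
    abort(sprintf("%d edge endpoint(s) reference missing node-layer tuples (state-set mismatch).",
                  sum(bad)))
  }
  structure(list(nodes = nodes, edges = edges, states = seq_len(K),
                 targets = targets, markers = markers,
                 state_order = state_order,
                 signaling_threshold = signaling_threshold),
            class = "emt_multilayer")
}

#' @export
print.emt_multilayer <- function(x, ...) {
  cat(sprintf("<emt_multilayer> %d states x 3 hierarchy layers; %d node-layer tuples, %d edges\n",
              length(x$states), nrow(x$nodes), nrow(x$edges)))
  print(dplyr::count(x$edges, .data$kind))
  invisible(x)
}

#' @rdname tidy_emtnet
#' @method tidy emt_multilayer
#' @export
tidy.emt_multilayer <- function(x, ...) as_tibble(x$edges)

#' @rdname tidy_emtnet
#' @method glance emt_multilayer
#' @export
glance.emt_multilayer <- function(x, ...) {
  tibble(
    n_states = length(x$states),
    n_targets = length(x$targets),
    n_markers = length(x$markers),
    n_node_layer_tuples = nrow(x$nodes),
    n_edges = nrow(x$edges),
    signaling_threshold = x$signaling_threshold
  )
}

#' Node strength of the cluster signaling network
#'
#' In-strength of a state is the sum of its incoming edge weights
#' (column sum); out-strength the sum of outgoing weights (row sum).
#'
#' @param Pc `K x K` signaling matrix or [cluster_signaling()] result.
#' @param mode `"in"` or `"out"`.
#' @return Named numeric vector of length `K`.
#' @export
node_strength <- function(Pc, mode = c("in", "out")) {
  M <- if (inherits(Pc, "emt_cluster_signaling")) Pc$Pc else Pc
  mode <- match.arg(mode)
  s <- if (mode == "in") colSums(M) else rowSums(M)
  setNames(s, sprintf("S%d", seq_along(s)))
}

signaling_graph <- function(M, weights_as = c("cost", "affinity")) {
  weights_as <- match.arg(weights_as)
  A <- M
  diag(A) <- 0
  if (weights_as == "affinity") {
    A[A > 0] <- 1 / A[A > 0]
  }
  igraph::graph_from_adjacency_matrix(A, mode = "directed", weighted = TRUE)
}

#' Normalized closeness centrality of the cluster signaling network
#'
#' Shortest paths treat edge weights as costs (path lengths), so a state
#' receiving strong (heavy) signaling edges sits *farther* from the rest and
#' has *lower* in-closeness -- the signature of a receiver. For node `v`
#' with `r_v` reachable other nodes at total distance `D_v`,
#' `closeness(v) = (r_v / D_v) * (r_v / (K - 1))`; unreachable nodes give 0.
#' `weights_as = "affinity"` instead uses `1/weight` as the cost.
#'
#' @inheritParams node_strength
#' @param weights_as `"cost"` (default) or `"affinity"`.
#' @return Named numeric vector of length `K`.
#' @export
node_closeness <- function(Pc, mode = c("in", "out"),
                           weights_as = c("cost", "affinity")) {
  M <- if (inherits(Pc, "emt_cluster_signaling")) Pc$Pc else Pc
  mode <- match.arg(mode)
  K <- nrow(M)
  if (K < 2) abort("closeness needs at least 2 states.")
  g <- signaling_graph(M, weights_as)
  D <- igraph::distances(g, mode = if (mode == "out") "out" else "in",
                         algorithm = "dijkstra")
  out <- vapply(seq_len(K), function(v) {
    d <- D[v, -v]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0 || sum(d[reach]) == 0) return(0)
    (r / sum(d[reach])) * (r / (K - 1))
  }, numeric(1))
  setNames(out, sprintf("S%d", seq_len(K)))
}

#' PageRank centrality of the cluster signaling network
#'
#' Weighted PageRank by power iteration: transition probabilities are
#' proportional to out-edge weights, dangling states redistribute uniformly,
#' and teleportation is uniform. States with high PageRank are the signaling
#' hubs of the communication network. Iterates until the L1 change drops
#' below `tol`; the result sums to 1.
#'
#' @inheritParams node_strength
#' @param damping Damping factor in `(0, 1)`; default 0.85.
#' @param tol L1 convergence tolerance; default `1e-12`.
#' @param max_iter Iteration cap (error on non-convergence).
#' @return Named numeric probability vector of length `K`.
#' @export
node_pagerank <- function(Pc, damping = 0.85, tol = 1e-12, max_iter = 1000L) {
  M <- if (inherits(Pc, "emt_cluster_signaling")) Pc$Pc else Pc
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  assert_fraction(damping, "damping", 0, 1, lo_open = TRUE, hi_open = TRUE)
  K <- nrow(M)
  out <- rowSums(M)
  dangling <- out <= 0
  P <- M
  P[!dangling, ] <- P[!dangling, , drop = FALSE] / out[!dangling]
  P[dangling, ] <- 0
  p <- rep(1 / K, K)
  for (it in seq_len(max_iter)) {
    p_new <- damping * (drop(crossprod(P, p)) + sum(p[dangling]) / K) +
      (1 - damping) / K
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new / sum(p_new)
      return(setNames(p, sprintf("S%d", seq_len(K))))
    }
    p <- p_new
  }
  abort("PageRank power iteration did not converge within `max_iter`.")
}

#' All centralities of the cluster signaling network in one table
#'
#' @inheritParams node_strength
#' @param damping PageRank damping factor.
#' @param weights_as Closeness cost semantics, see [node_closeness()].
#' @return Tibble with `state`, `in_strength`, `out_strength`,
#'   `in_closeness`, `out_closeness`, `pagerank`.
#' @export
signaling_centrality <- function(Pc, damping = 0.85,
                                 weights_as = c("cost", "affinity")) {
  M <- if (inherits(Pc, "emt_cluster_signaling")) Pc$Pc else Pc
  weights_as <- match.arg(weights_as)
  tibble(
    state = seq_len(nrow(M)),
    in_strength = unname(node_strength(M, "in")),
    out_strength = unname(node_strength(M, "out")),
    in_closeness = unname(node_closeness(M, "in", weights_as)),
    out_closeness = unname(node_closeness(M, "out", weights_as)),
    pagerank = unname(node_pagerank(M, damping = damping))
  )
}
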