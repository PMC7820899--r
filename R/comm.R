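#' Cell-cell signaling probability for one ligand-receptor pair
#'
#' Quantifies the probability that a signal passes from sender cell `i` to
#' receiver cell `j` from weighted co-expression of the pathway components:
#' with `l_i` the ligand in cell `i`, `r_j` the receptor in cell `j`, `u_j`
#' and `d_j` the mean up-/down-regulated target expression in `j`,
#' \deqn{\alpha_{ij} = e^{-1/(l_i r_j)},\quad \beta_j = e^{-1/\bar u_j},\quad
#'       \gamma_j = e^{-\bar d_j},}
#' (each exponential-saturation factor is 0 when its argument is 0; the
#' target factors are 1 when the corresponding target list is empty), and
#' `P[i, j]` is `alpha * beta * gamma` normalized over receivers `j` so that
#' each row sums to 1 or is all-zero. Self-pairs (`i = j`, autocrine
#' signaling) are retained.
#'
#' @param X Cell x gene matrix of log-transformed expression (all genes, no
#'   gene filtering).
#' @param ligand,receptor Gene ids of the pair (must be present in `X`).
#' @param targets_up,targets_down Character vectors of target gene ids
#'   (possibly empty).
#' @return An `n x n` signaling probability matrix with cell ids as dimnames
#'   and attribute `pair_id`.
#' @export
lr_signaling_probability <- function(X, ligand, receptor,
                                     targets_up = character(),
                                     targets_down = character()) {
  validate_expression(X)
  missing <- setdiff(c(ligand, receptor, targets_up, targets_down), colnames(X))
  if (length(missing)) {
    abort(sprintf("gene(s) not present in the expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  l <- X[, ligand]
  r <- X[, receptor]
  lr <- l %o% r
  alpha <- matrix(0, nrow(X), nrow(X))
  pos <- lr > 0
  alpha[pos] <- exp(-1 / lr[pos])

  beta <- if (length(targets_up)) {
    u <- rowMeans(X[, targets_up, drop = FALSE])
    ifelse(u > 0, exp(-1 / u), 0)
  } else rep(1, nrow(X))
  gamma <- if (length(targets_down)) {
    d <- rowMeans(X[, targets_down, drop = FALSE])
    exp(-d)
  } else rep(1, nrow(X))

  P <- sweep(alpha, 2, beta * gamma, "*")
  rs <- rowSums(P)
  nz <- rs > 0
  P[nz, ] <- P[nz, , drop = FALSE] / rs[nz]
  dimnames(P) <- list(rownames(X), rownames(X))
  attr(P, "pair_id") <- paste0(ligand, "->", receptor)
  P
}

#' Consensus signaling over several ligand-receptor pairs
#'
#' Element-wise mean of the per-pair cell-cell signaling probability
#' matrices; order-invariant.
#'
#' @param matrices List of equally shaped signaling matrices.
#' @return A matrix of the same shape with attribute `pair_id = "consensus"`.
#' @export
consensus_signaling <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0) {
    abort("`matrices` must be a non-empty list.")
  }
  dims <- dim(matrices[[1]])
  if (!all(vapply(matrices, function(m) identical(dim(m), dims), logical(1)))) {
    abort("all signaling matrices must have the same shape.")
  }
  P <- Reduce(`+`, matrices) / length(matrices)
  attr(P, "pair_id") <- "consensus"
  P
}

#' Aggregate cell-cell signaling to cluster-cluster signaling
#'
#' The signaling probability from cluster `u` to cluster `v` is
#' `Pc[u, v] = sum_{i in C_u, j in C_v} P[i, j] / (|C_u| |C_v|)`, zero when
#' either cluster is empty. `support[u, v]` counts the sender-receiver cell
#' pairs with a strictly positive probability.
#'
#' @param P Cell-cell signaling matrix.
#' @param labels Per-cell cluster index in `1..K`.
#' @param K Number of clusters.
#' @return An object of class `emt_cluster_signaling`: list with `Pc`
#'   (`K x K`), `support` (`K x K` integer counts), `sizes`.
#' @export
cluster_signaling <- function(P, labels, K) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  K <- assert_count(K, "K")
  labels <- as.integer(labels)
  if (length(labels) != nrow(P)) abort("`labels` must have one entry per cell.")
  if (any(labels < 1 | labels > K)) abort("cluster labels must lie in 1..K.")
  Z <- matrix(0, nrow(P), K)
  Z[cbind(seq_along(labels), labels)] <- 1
  sizes <- colSums(Z)
  sums <- t(Z) %*% P %*% Z
  supp <- t(Z) %*% (P > 0) %*% Z
  denom <- sizes %o% sizes
  Pc <- ifelse(denom > 0, sums / pmax(denom, 1), 0)
  structure(list(Pc = Pc, support = matrix(as.integer(supp), K, K),
                 sizes = as.integer(sizes)),
            class = "emt_cluster_signaling")
}

#' @export
print.emt_cluster_signaling <- function(x, ...) {
  cat(sprintf("<emt_cluster_signaling> K = %d; max probability %.3f\n",
              nrow(x$Pc), max(x$Pc)))
  invisible(x)
}

#' @rdname tidy_emtnet
#' @method tidy emt_cluster_signaling
#' @export
tidy.emt_cluster_signaling <- function(x, ...) {
  K <- nrow(x$Pc)
  tidyr::expand_grid(sender = seq_len(K), receiver = seq_len(K)) |>
    dplyr::mutate(
      probability = x$Pc[cbind(.data$sender, .data$receiver)],
      support = x$support[cbind(.data$sender, .data$receiver)]
    )
}
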