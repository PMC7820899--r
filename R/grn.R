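# Discrete information-theoretic machinery for PID-based GRN inference.
# All estimators are plug-in (maximum likelihood) on contingency tables and
# report values in bits.

code_vector <- function(x) as.integer(factor(x)) - 1L

joint_counts <- function(x, y) {
  nx <- max(x) + 1L; ny <- max(y) + 1L
  matrix(tabulate(x + nx * y + 1L, nbins = nx * ny), nx, ny)
}

#' Uniform-width discretization of an expression matrix
#'
#' Bins each gene independently into equal-width bins over its observed
#' range, with the top bin right-closed. `n_bins = NULL` uses the Sturges
#' rule `max(2, ceiling(log2(n) + 1))`; a constant gene gets a single bin.
#' Partial information decomposition operates on these codes.
#'
#' @param X Cell x gene matrix.
#' @param method Currently only `"uniform_width"`.
#' @param n_bins Integer bin count, or `NULL` for the Sturges default.
#' @return An object of class `emt_discrete`: list with `codes` (0-based
#'   integer matrix), `n_bins` (per gene), `bin_edges` (per gene).
#' @export
discretize_matrix <- function(X, method = "uniform_width", n_bins = NULL) {
  method <- match.arg(method, "uniform_width")
  stopifnot(is.matrix(X), nrow(X) >= 2)
  n <- nrow(X)
  nb_default <- if (is.null(n_bins)) max(2L, ceiling(log2(n) + 1)) else
    assert_count(n_bins, "n_bins", min = 2L)
  codes <- matrix(0L, n, ncol(X), dimnames = dimnames(X))
  nb_out <- integer(ncol(X))
  edges <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    lo <- min(x); hi <- max(x)
    if (hi - lo < .Machine$double.eps) {
      nb_out[j] <- 1L
      edges[[j]] <- c(lo, hi)
    } else {
      nb <- nb_default
      width <- (hi - lo) / nb
      codes[, j] <- pmin(as.integer(floor((x - lo) / width)), nb - 1L)
      nb_out[j] <- nb
      edges[[j]] <- lo + width * (0:nb)
    }
  }
  structure(list(codes = codes, n_bins = nb_out, bin_edges = edges),
            class = "emt_discrete")
}

#' Mutual information of two discrete vectors (bits)
#'
#' Plug-in maximum-likelihood estimate
#' `I(X;Y) = sum p(x,y) log2[p(x,y) / (p(x) p(y))]`.
#'
#' @param x,y Discrete vectors of equal length (any coding).
#' @return Non-negative mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  N <- joint_counts(code_vector(x), code_vector(y))
  n <- sum(N)
  px <- rowSums(N) / n
  py <- colSums(N) / n
  p <- N / n
  terms <- p * log2(p / (px %o% py))
  max(sum(terms[N > 0]), 0)
}

# Specific information I_spec(Y = y; A) for every value of Y, in bits:
# sum_a p(a|y) [log2 p(y|a) - log2 p(y)], from the joint count table.
specific_information <- function(y, a) {
  N <- joint_counts(code_vector(y), code_vector(a))
  n <- sum(N)
  Ny <- rowSums(N)
  Na <- colSums(N)
  out <- numeric(nrow(N))
  for (yy in seq_len(nrow(N))) {
    if (Ny[yy] == 0) next
    nz <- which(N[yy, ] > 0)
    p_a_given_y <- N[yy, nz] / Ny[yy]
    p_y_given_a <- N[yy, nz] / Na[nz]
    out[yy] <- sum(p_a_given_y * (log2(p_y_given_a) - log2(Ny[yy] / n)))
  }
  out
}

#' Williams-Beer redundancy I_min of two sources about a target (bits)
#'
#' `I_min(Y; {X, Z}) = sum_y p(y) min(I_spec(Y=y; X), I_spec(Y=y; Z))`,
#' where the specific information of a source about a target value is
#' `I_spec(Y=y; A) = sum_a p(a|y) [log2(1/p(y)) - log2(1/p(y|a))]`.
#' Satisfies `0 <= I_min <= min(I(X;Y), I(Z;Y))`.
#'
#' @param y Target discrete vector.
#' @param x,z Source discrete vectors, same length as `y`.
#' @return Redundancy in bits.
#' @export
redundancy_imin <- function(y, x, z) {
  stopifnot(length(y) == length(x), length(y) == length(z))
  yc <- code_vector(y)
  py <- tabulate(yc + 1L) / length(yc)
  sx <- specific_information(y, x)
  sz <- specific_information(y, z)
  max(sum(py * pmin(sx, sz)), 0)
}

#' Unique information of a source about a target, relative to another source
#'
#' `U_z(X -> Y) = I(X;Y) - I_min(Y; {X, Z})`, the part of the information
#' `X` carries about `Y` that the other source `Z` does not share (bits,
#' clamped at 0 against floating-point round-off).
#'
#' @param x Source of interest.
#' @param y Target.
#' @param z The other source.
#' @return Unique information in bits.
#' @export
unique_information <- function(x, y, z) {
  max(mutual_information(x, y) - redundancy_imin(y, x, z), 0)
}

#' Proportional unique contribution (PUC) matrix
#'
#' For every gene pair `(X, Y)` sums, over all other genes `Z`, both
#' directional unique informations normalized by the pair's mutual
#' information:
#' `U[X,Y] = sum_Z [U_Z(X->Y) + U_Z(Y->X)] / I(X;Y)` (a term is 0 when
#' `I(X;Y) = 0`). Symmetric with zero diagonal.
#'
#' @param D An [discretize_matrix()] result, or a discrete cell x gene
#'   matrix.
#' @return A `g x g` symmetric non-negative matrix with gene dimnames.
#' @export
puc_matrix <- function(D) {
  codes <- if (inherits(D, "emt_discrete")) D$codes else D
  stopifnot(is.matrix(codes))
  g <- ncol(codes)
  if (g < 3) abort("PUC needs at least 3 genes (no third gene otherwise).")
  cols <- lapply(seq_len(g), function(j) code_vector(codes[, j]))
  MI <- matrix(0, g, g)
  for (a in seq_len(g - 1)) for (b in (a + 1):g) {
    MI[a, b] <- MI[b, a] <- mutual_information(cols[[a]], cols[[b]])
  }
  U <- matrix(0, g, g)
  for (a in seq_len(g - 1)) for (b in (a + 1):g) {
    if (MI[a, b] <= 0) next
    acc <- 0
    for (z in seq_len(g)) {
      if (z == a || z == b) next
      u_ab <- max(MI[a, b] - redundancy_imin(cols[[b]], cols[[a]], cols[[z]]), 0)
      u_ba <- max(MI[a, b] - redundancy_imin(cols[[a]], cols[[b]], cols[[z]]), 0)
      acc <- acc + u_ab + u_ba
    }
    U[a, b] <- U[b, a] <- acc / MI[a, b]
  }
  dimnames(U) <- list(colnames(codes), colnames(codes))
  U
}

#' Edge confidence from per-gene empirical CDFs of PUC scores
#'
#' The confidence of the edge between genes `X` and `Y` is
#' `c = F_X(U[X,Y]) + F_Y(U[X,Y])`, where `F_X` is the right-continuous
#' empirical CDF of all PUC scores involving gene `X` (its off-diagonal
#' row). Entries lie in `(0, 2]`; the diagonal is 0.
#'
#' @param U A symmetric PUC matrix from [puc_matrix()].
#' @return A `g x g` symmetric confidence matrix.
#' @export
confidence_network <- function(U) {
  stopifnot(is.matrix(U), nrow(U) == ncol(U))
  g <- nrow(U)
  if (g < 3) abort("confidence needs at least 3 genes.")
  Fs <- lapply(seq_len(g), function(i) ecdf(U[i, -i]))
  C <- matrix(0, g, g, dimnames = dimnames(U))
  for (a in seq_len(g - 1)) for (b in (a + 1):g) {
    C[a, b] <- C[b, a] <- Fs[[a]](U[a, b]) + Fs[[b]](U[a, b])
  }
  C
}

#' State-specific gene regulatory network by PID confidence
#'
#' Restricts the expression matrix to the cells of one cell state and the
#' listed genes, discretizes, computes the PUC matrix and edge confidences,
#' keeps the top `ceiling(keep_fraction * choose(g, 2))` edges by confidence
#' (ties broken by the lexicographic gene-id pair), and rescales weights so
#' the maximum kept weight equals `max_weight_norm` (default 2, keeping
#' networks comparable across datasets; default `keep_fraction` 0.30).
#'
#' @param X Cell x gene matrix (log-transformed expression).
#' @param labels Per-cell cluster index.
#' @param state Cluster index defining the state.
#' @param genes Gene ids to include (>= 3, present in `X`).
#' @param keep_fraction Fraction of candidate edges kept.
#' @param max_weight_norm Normalized maximum edge weight.
#' @param n_bins Passed to [discretize_matrix()].
#' @return A tibble of class `emt_state_grn` with columns `gene_x`,
#'   `gene_y`, `weight`, and attributes `state`, `genes`, `keep_fraction`,
#'   `max_weight_norm`.
#' @export
state_grn <- function(X, labels, state, genes, keep_fraction = 0.30,
                      max_weight_norm = 2, n_bins = NULL) {
  validate_expression(X)
  stopifnot(length(labels) == nrow(X))
  assert_fraction(keep_fraction, "keep_fraction", 0, 1, lo_open = TRUE)
  if (!is.numeric(max_weight_norm) || max_weight_norm <= 0) {
    abort("`max_weight_norm` must be positive.")
  }
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, colnames(X))
  if (length(missing)) {
    abort(sprintf("state %d: gene(s) absent from expression matrix: %s",
                  state, paste(missing, collapse = ", ")))
  }
  cells <- which(labels == state)
  if (length(cells) < 5) {
    abort(sprintf("state %d has fewer than 5 cells.", state))
  }
  if (length(genes) < 3) {
    abort(sprintf("state %d: need at least 3 genes for PID.", state))
  }
  Xs <- X[cells, genes, drop = FALSE]
  C <- confidence_network(puc_matrix(discretize_matrix(Xs, n_bins = n_bins)))

  idx <- which(upper.tri(C), arr.ind = TRUE)
  cand <- tibble(
    gene_x = pmin(genes[idx[, 1]], genes[idx[, 2]]),
    gene_y = pmax(genes[idx[, 1]], genes[idx[, 2]]),
    weight = C[idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$gene_x, .data$gene_y)
  m <- ceiling(keep_fraction * nrow(cand))
  kept <- head(cand, m)
  kept$weight <- kept$weight * max_weight_norm / max(kept$weight)
  structure(kept, class = c("emt_state_grn", class(kept)),
            state = state, genes = genes,
            keep_fraction = keep_fraction, max_weight_norm = max_weight_norm)
}
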