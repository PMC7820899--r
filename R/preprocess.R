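#' Filter low-quality cells by detected-gene coverage
#'
#' A gene is *detected* if it is non-zero in at least one cell. A cell is kept
#' when the fraction of detected genes it expresses (non-zero) is at least
#' `min_detected_fraction`. The default of 0.95 is deliberately strict and is
#' exposed as a parameter; cell order is preserved and the operation is
#' idempotent.
#'
#' @param X Cell x gene expression matrix.
#' @param min_detected_fraction Minimum fraction of detected genes a cell must
#'   express, in `(0, 1]`.
#' @return The filtered matrix.
#' @export
filter_cells <- function(X, min_detected_fraction = 0.95) {
  validate_expression(X)
  assert_fraction(min_detected_fraction, "min_detected_fraction",
                  0, 1, lo_open = TRUE)
  detected <- colSums(X > 0) > 0
  if (!any(detected)) abort("all cells filtered: no detected genes.")
  frac <- rowMeans(X[, detected, drop = FALSE] > 0)
  keep <- frac >= min_detected_fraction
  if (!any(keep)) abort("all cells filtered: no cell reaches `min_detected_fraction`.")
  X[keep, , drop = FALSE]
}

#' Bimodality index of a gene's expression profile
#'
#' Fits a two-component equal-variance Gaussian mixture to `log1p(x)` by EM,
#' initialized deterministically from the 10% and 90% quantiles, and returns
#' the bimodality index `BI = |mu1 - mu2| / sigma * sqrt(p (1 - p))`. Larger
#' values indicate a cleaner two-state (on/off) gene. Constant vectors score 0.
#'
#' @param x Numeric non-negative expression vector, length >= 4.
#' @param max_iter,tol EM iteration controls.
#' @return A single non-negative score.
#' @export
bimodality_score <- function(x, max_iter = 200L, tol = 1e-8) {
  if (length(x) < 4) abort("`x` must have length >= 4.")
  y <- log1p(x)
  if (max(y) - min(y) < .Machine$double.eps) return(0)
  mu <- unname(quantile(y, c(0.1, 0.9), names = FALSE))
  if (mu[1] == mu[2]) mu <- range(y)
  sig <- max(sd(y), 1e-3)
  p <- 0.5
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d1 <- p * stats::dnorm(y, mu[1], sig)
    d2 <- (1 - p) * stats::dnorm(y, mu[2], sig)
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    r <- d1 / tot
    ll <- sum(log(tot))
    p <- mean(r)
    p <- min(max(p, 1e-6), 1 - 1e-6)
    mu[1] <- sum(r * y) / sum(r)
    mu[2] <- sum((1 - r) * y) / sum(1 - r)
    sig <- sqrt(sum(r * (y - mu[1])^2 + (1 - r) * (y - mu[2])^2) / length(y))
    sig <- max(sig, 1e-3)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  abs(mu[1] - mu[2]) / sig * sqrt(p * (1 - p))
}

#' Select the most bimodal genes
#'
#' Ranks genes by [bimodality_score()] (descending; ties broken by gene id)
#' and returns the top `n_top`. The default of 3000 follows the convention of
#' selecting the 3,000 most bimodal genes for downstream analysis; it is
#' capped at the number of genes present.
#'
#' @param X Cell x gene expression matrix.
#' @param n_top Number of genes to keep (default 3000, capped at `ncol(X)`).
#' @return A tibble of class `gene_selection` with columns `gene_id`, `score`,
#'   sorted by decreasing score.
#' @export
select_genes <- function(X, n_top = 3000L) {
  validate_expression(X)
  if (!is.numeric(n_top) || length(n_top) != 1 || n_top < 1) {
    abort("`n_top` must be a positive integer.")
  }
  n_top <- min(as.integer(n_top), ncol(X))
  scores <- vapply(seq_len(ncol(X)), function(j) bimodality_score(X[, j]),
                   numeric(1))
  out <- tibble(gene_id = colnames(X), score = scores) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id) |>
    head(n_top)
  class(out) <- c("gene_selection", class(out))
  out
}
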