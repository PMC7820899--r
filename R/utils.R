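#' Validate a cell-by-gene expression matrix
#'
#' Checks that `X` is a numeric matrix with non-negative entries and unique,
#' non-empty row (cell) and column (gene) names. All pipeline stages consume
#' matrices in this orientation: rows are cells, columns are genes.
#'
#' @param X A numeric matrix, cells in rows, genes in columns.
#' @param arg Name used in error messages.
#' @return `X`, invisibly, after validation.
#' @keywords internal
validate_expression <- function(X, arg = "X") {
  if (!is.matrix(X) || !is.numeric(X)) {
    abort(sprintf("`%s` must be a numeric cell x gene matrix.", arg))
  }
  if (anyNA(X) || any(X < 0)) {
    abort(sprintf("`%s` must be non-negative with no missing values.", arg))
  }
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    abort(sprintf("`%s` must carry cell ids as rownames and gene ids as colnames.", arg))
  }
  if (anyDuplicated(rownames(X))) abort("duplicate cell ids.")
  if (anyDuplicated(colnames(X))) abort("duplicate gene ids.")
  invisible(X)
}

#' Log-transform counts for downstream analysis
#'
#' All similarity, signaling and information-theoretic stages operate on
#' `log1p`-transformed values of the (selected) genes.
#'
#' @param X Non-negative cell x gene matrix.
#' @return `log1p(X)` with dimnames preserved.
#' @export
log_transform <- function(X) {
  validate_expression(X)
  log1p(X)
}

#' Run code under a local seed without disturbing the global RNG
#' @noRd
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assert_fraction <- function(x, arg, lo = 0, hi = 1,
                            lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%g, %g%s.",
                  arg, if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]"))
  }
  invisible(x)
}

assert_count <- function(x, arg, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == as.integer(x) && x >= min
  if (!ok) abort(sprintf("`%s` must be an integer >= %d.", arg, min))
  invisible(as.integer(x))
}

#' Match inferred cluster labels to reference labels
#'
#' Greedy maximum-overlap assignment on the confusion matrix between two hard
#' labelings of the same cells. Used to compare an inferred clustering (whose
#' label indices are arbitrary) against a ground-truth labeling, e.g. before
#' asking whether an inferred trajectory equals a planted one.
#'
#' @param inferred,reference Integer label vectors of equal length (1-based).
#' @return Integer vector `map` with `map[k]` the reference label matched to
#'   inferred label `k`.
#' @export
match_labels <- function(inferred, reference) {
  stopifnot(length(inferred) == length(reference))
  ki <- sort(unique(inferred)); kr <- sort(unique(reference))
  conf <- table(factor(inferred, levels = ki), factor(reference, levels = kr))
  map <- rep(NA_integer_, max(ki))
  used <- logical(length(kr))
  for (step in seq_len(min(length(ki), length(kr)))) {
    idx <- which(conf == max(conf), arr.ind = TRUE)[1, , drop = TRUE]
    map[ki[idx[1]]] <- kr[idx[2]]
    conf[idx[1], ] <- -1
    conf[, idx[2]] <- -1
  }
  map
}
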