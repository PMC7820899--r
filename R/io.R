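#' Read a cell x gene expression matrix
#'
#' CSV layout: header row of gene names, first column of cell ids. MTX
#' layout: a directory (or `matrix.mtx` path) holding `matrix.mtx` (genes x
#' cells, MatrixMarket), `genes.tsv` and `barcodes.tsv`. Duplicate ids and
#' dimension mismatches are rejected.
#'
#' @param path File (CSV) or directory/`matrix.mtx` path (MTX).
#' @param format `"auto"` (by extension), `"csv"` or `"mtx"`.
#' @return A validated cell x gene numeric matrix.
#' @export
read_expression <- function(path, format = c("auto", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) abort(sprintf("parse error in %s: need id column plus genes.", path))
    ids <- as.character(df[[1]])
    genes <- colnames(df)[-1]
    if (anyDuplicated(ids)) abort("duplicate cell ids in CSV.")
    if (anyDuplicated(genes)) abort("duplicate gene columns in CSV.")
    X <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(X)) abort(sprintf("parse error in %s: non-numeric entries.", path))
    rownames(X) <- ids
  } else {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- file.path(dir, "matrix.mtx")
    gf <- file.path(dir, "genes.tsv")
    bf <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx, gf, bf)) if (!file.exists(f)) abort(sprintf("missing file: %s", f))
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      abort("reading MTX requires the Matrix package.")
    }
    M <- as.matrix(Matrix::readMM(mtx))
    genes <- utils::read.table(gf, sep = "\t", stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(bf, sep = "\t", stringsAsFactors = FALSE)[[1]]
    if (nrow(M) != length(genes)) abort("dimension error: gene count does not match matrix rows.")
    if (ncol(M) != length(cells)) abort("dimension error: barcode count does not match matrix columns.")
    if (anyDuplicated(genes)) abort("duplicate gene ids in genes.tsv.")
    if (anyDuplicated(cells)) abort("duplicate barcodes in barcodes.tsv.")
    X <- t(M)
    dimnames(X) <- list(cells, genes)
  }
  validate_expression(X)
  X
}

#' Write a cell x gene expression matrix
#'
#' @param X Cell x gene matrix.
#' @param path CSV file path, or a directory for MTX output.
#' @param format `"csv"` or `"mtx"` (genes x cells `matrix.mtx` plus
#'   `genes.tsv` and `barcodes.tsv`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path, format = c("csv", "mtx")) {
  validate_expression(X)
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(cell_id = rownames(X), X, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      abort("writing MTX requires the Matrix package.")
    }
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(X), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    utils::write.table(colnames(X), file.path(path, "genes.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    utils::write.table(rownames(X), file.path(path, "barcodes.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read / write a pathway specification as JSON
#'
#' Schema: `{"pathway": str, "pairs": [{"ligand": str, "receptor": str}],
#' "targets_up": [str], "targets_down": [str]}`.
#'
#' @param path JSON file path.
#' @return [read_pathway_spec()] returns an `emt_pathway_spec`;
#'   [write_pathway_spec()] returns `path` invisibly.
#' @export
read_pathway_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("pathway", "pairs", "targets_up", "targets_down")) {
    if (is.null(j[[f]])) abort(sprintf("pathway JSON missing field `%s`.", f))
  }
  pairs <- as_tibble(j$pairs)
  if (any(pairs$ligand == pairs$receptor)) {
    abort("a ligand-receptor pair may not reuse the same gene.")
  }
  structure(list(pathway = j$pathway, pairs = pairs,
                 targets_up = as.character(j$targets_up),
                 targets_down = as.character(j$targets_down)),
            class = "emt_pathway_spec")
}

#' @rdname read_pathway_spec
#' @param spec An `emt_pathway_spec`.
#' @export
write_pathway_spec <- function(spec, path) {
  stopifnot(inherits(spec, "emt_pathway_spec"))
  jsonlite::write_json(
    list(pathway = spec$pathway,
         pairs = as.data.frame(spec$pairs),
         targets_up = spec$targets_up,
         targets_down = spec$targets_down),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
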