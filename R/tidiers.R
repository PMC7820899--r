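#' Tidy and glance methods for emtnet result objects
#'
#' `tidy()` returns one row per atomic result (cell, edge, marker); `glance()`
#' returns a one-row model summary. Methods follow the broom convention.
#'
#' @param x An emtnet result object.
#' @param ... Unused.
#' @name tidy_emtnet
NULL

#' @rdname tidy_emtnet
#' @method tidy emt_cluster_model
#' @export
tidy.emt_cluster_model <- function(x, ...) {
  ids <- rownames(x$H) %||% as.character(seq_len(nrow(x$H)))
  tibble(cell_id = ids, cluster = x$labels, cpi = unname(x$cpi)) |>
    dplyr::bind_cols(as_tibble(x$H, .name_repair = ~ sprintf("H%d", seq_len(x$K))))
}

#' @rdname tidy_emtnet
#' @method glance emt_cluster_model
#' @export
glance.emt_cluster_model <- function(x, ...) {
  tibble(n_cells = nrow(x$H), K = x$K, mean_cpi = mean(x$cpi),
         max_cpi = max(x$cpi),
         converged = isTRUE(attr(x$H, "converged")))
}

#' @rdname tidy_emtnet
#' @method tidy emt_marker_table
#' @export
tidy.emt_marker_table <- function(x, ...) as_tibble(x$top_markers)

#' @rdname tidy_emtnet
#' @method glance emt_cluster_signaling
#' @export
glance.emt_cluster_signaling <- function(x, ...) {
  tibble(K = nrow(x$Pc), total_probability = sum(x$Pc),
         max_probability = max(x$Pc),
         n_supported_pairs = sum(x$support > 0))
}

#' @rdname tidy_emtnet
#' @method tidy emt_dataset
#' @export
tidy.emt_dataset <- function(x, ...) {
  tibble(
    cell_id = rownames(x$expression),
    cluster = x$true_labels,
    is_tc = x$is_tc,
    time = unname(x$time_labels)
  ) |>
    dplyr::bind_cols(as_tibble(x$true_membership,
                               .name_repair = ~ sprintf("H%d", seq_len(ncol(x$true_membership)))))
}
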