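#' Plot the cell plasticity index by cluster
#'
#' Violin/jitter plot of CPI per hard cluster; transition cells sit in the
#' upper tail.
#'
#' @param model An `emt_cluster_model`.
#' @return A ggplot object.
#' @export
plot_cpi <- function(model) {
  stopifnot(inherits(model, "emt_cluster_model"))
  df <- tidy(model)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$cluster), .data$cpi)) +
    ggplot2::geom_violin(fill = "grey85", scale = "width") +
    ggplot2::geom_jitter(width = 0.15, size = 0.5, alpha = 0.5) +
    ggplot2::labs(x = "cluster", y = "cell plasticity index (CPI)") +
    ggplot2::theme_minimal()
}

#' Plot cluster-cluster transition weights
#'
#' Heat map of the symmetric transition-cell fraction matrix; the trajectory
#' follows the heavy off-diagonal band.
#'
#' @param W Matrix from [cluster_transition_weights()].
#' @return A ggplot object.
#' @export
plot_cluster_graph <- function(W) {
  stopifnot(is.matrix(W))
  K <- nrow(W)
  df <- tidyr::expand_grid(u = seq_len(K), v = seq_len(K)) |>
    dplyr::mutate(tc_fraction = W[cbind(.data$u, .data$v)])
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$v), factor(.data$u),
                                   fill = .data$tc_fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "cluster", y = "cluster", fill = "TC fraction") +
    ggplot2::theme_minimal()
}

#' Plot the cluster-cluster signaling network
#'
#' Sender x receiver heat map of signaling probabilities, dot size giving the
#' number of supporting cell pairs.
#'
#' @param x An `emt_cluster_signaling` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emt_cluster_signaling
#' @export
autoplot.emt_cluster_signaling <- function(x, ...) {
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$receiver), factor(.data$sender))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$support,
                                     colour = .data$probability)) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "receiver state", y = "sender state",
                  colour = "P(u,v)", size = "supporting\ncell pairs") +
    ggplot2::theme_minimal()
}

#' Plot centrality profiles of the signaling network
#'
#' @param centrality Tibble from [signaling_centrality()].
#' @return A ggplot object.
#' @export
plot_centrality <- function(centrality) {
  df <- tidyr::pivot_longer(centrality, -"state",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$state), .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "cell state", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
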