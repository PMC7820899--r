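#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with its
#' default. Unknown arguments are rejected; supplying both transition-cell
#' selectors is rejected before any stage runs.
#'
#' @param min_detected_fraction Cell-filter coverage threshold (see
#'   [filter_cells()]).
#' @param n_top_genes Bimodal genes kept (see [select_genes()]).
#' @param k_min,k_max Eigen-gap search range.
#' @param k_values,d_values,n_seeds Consensus clustering grid.
#' @param tc_cpi_threshold,tc_top_fraction Transition-cell selector (at most
#'   one; default mode is `tc_top_fraction = 0.2`).
#' @param start_cluster Trajectory start; `NULL` uses the top terminal-state
#'   candidate.
#' @param top_markers Markers per cluster for the marker layer.
#' @param keep_fraction_grn,keep_fraction_expr,keep_fraction_cross Edge
#'   pruning fractions for the state GRNs and the two inter-layer link
#'   classes.
#' @param signaling_threshold Layer-1 edge threshold.
#' @param damping PageRank damping factor.
#' @param max_weight_norm GRN weight normalization cap.
#' @param n_bins Discretization bins (`NULL` = Sturges).
#' @param seed Master seed for all stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_detected_fraction = 0.95,
                            n_top_genes = 3000L,
                            k_min = 3L, k_max = 8L,
                            k_values = 3:8, d_values = c(4, 6, 8, 10),
                            n_seeds = 10L,
                            tc_cpi_threshold = NULL, tc_top_fraction = NULL,
                            start_cluster = NULL,
                            top_markers = 5L,
                            keep_fraction_grn = 0.30,
                            keep_fraction_expr = 0.20,
                            keep_fraction_cross = 0.015,
                            signaling_threshold = 0.5,
                            damping = 0.85,
                            max_weight_norm = 2,
                            n_bins = NULL,
                            seed = 1L) {
  if (!is.null(tc_cpi_threshold) && !is.null(tc_top_fraction)) {
    abort("set at most one of `tc_cpi_threshold` and `tc_top_fraction`.")
  }
  assert_fraction(min_detected_fraction, "min_detected_fraction", 0, 1,
                  lo_open = TRUE)
  assert_count(n_top_genes, "n_top_genes")
  assert_fraction(keep_fraction_grn, "keep_fraction_grn", 0, 1, lo_open = TRUE)
  assert_fraction(keep_fraction_expr, "keep_fraction_expr", 0, 1, lo_open = TRUE)
  assert_fraction(keep_fraction_cross, "keep_fraction_cross", 0, 1, lo_open = TRUE)
  assert_fraction(signaling_threshold, "signaling_threshold", 0, 1)
  assert_fraction(damping, "damping", 0, 1, lo_open = TRUE, hi_open = TRUE)
  structure(list(
    min_detected_fraction = min_detected_fraction,
    n_top_genes = as.integer(n_top_genes),
    k_min = as.integer(k_min), k_max = as.integer(k_max),
    k_values = as.integer(k_values), d_values = as.integer(d_values),
    n_seeds = as.integer(n_seeds),
    tc_cpi_threshold = tc_cpi_threshold,
    tc_top_fraction = tc_top_fraction,
    start_cluster = start_cluster,
    top_markers = as.integer(top_markers),
    keep_fraction_grn = keep_fraction_grn,
    keep_fraction_expr = keep_fraction_expr,
    keep_fraction_cross = keep_fraction_cross,
    signaling_threshold = signaling_threshold,
    damping = damping,
    max_weight_norm = max_weight_norm,
    n_bins = n_bins,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full multiscale EMT analysis
#'
#' Executes preprocessing, consensus soft clustering with eigen-gap cluster
#' selection, transition-cell and trajectory inference, ligand-receptor
#' cluster signaling, per-state PID GRNs, multilayer-network assembly and
#' centrality analysis, writing every artifact plus a parameter manifest to
#' `outdir`. Re-running with an identical configuration and input reproduces
#' identical outputs.
#'
#' @param X Cell x gene count matrix (e.g. `$expression` of a synthetic
#'   dataset, or from [read_expression()]).
#' @param pathway An `emt_pathway_spec`.
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list with `selection`, `similarity`, `model`, `tcs`,
#'   `W`, `terminals`, `path`, `pseudotime`, `markers`, `signaling`,
#'   `centrality`, `state_grns`, `marker_grns`, `multilayer`, `manifest`.
#' @export
run_emt_pipeline <- function(X, pathway, config = pipeline_config(),
                             outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(pathway, "emt_pathway_spec"))
  validate_expression(X)

  Xf <- stage("filter_cells", filter_cells(X, config$min_detected_fraction))
  sel <- stage("select_genes", select_genes(Xf, config$n_top_genes))
  Xl <- log_transform(Xf[, sel$gene_id, drop = FALSE])

  S <- stage("consensus_similarity", consensus_similarity(
    Xl, k_values = config$k_values, d_values = config$d_values,
    n_seeds = config$n_seeds, seed = config$seed))
  K <- stage("estimate_num_clusters", estimate_num_clusters(
    S, k_min = config$k_min, k_max = min(config$k_max, nrow(S) - 1L)))
  H <- stage("soft_cluster", soft_cluster(S, K, seed = config$seed))
  model <- cluster_model(H)

  tcs <- stage("identify_transition_cells", identify_transition_cells(
    model, cpi_threshold = config$tc_cpi_threshold,
    top_fraction = config$tc_top_fraction))
  W <- cluster_transition_weights(tcs)
  terminals <- select_terminal_states(W)
  start <- config$start_cluster %||% terminals[1]
  path <- stage("infer_trajectory", infer_trajectory(W, start))
  pt <- compute_pseudotime(model$H, path)
  markers <- stage("infer_marker_genes",
                   infer_marker_genes(Xl, model$H, config$top_markers))

  Xall <- log_transform(Xf) # signaling uses all genes, no gene filtering
  mats <- stage("lr_signaling", purrr::map(seq_len(nrow(pathway$pairs)), function(i) {
    lr_signaling_probability(Xall, pathway$pairs$ligand[i],
                             pathway$pairs$receptor[i],
                             pathway$targets_up, pathway$targets_down)
  }))
  P <- consensus_signaling(mats)
  cs <- stage("cluster_signaling", cluster_signaling(P, model$labels, K))
  centr <- stage("centrality", signaling_centrality(cs, damping = config$damping))

  target_set <- intersect(c(pathway$targets_up, pathway$targets_down),
                          sel$gene_id)
  marker_set <- unique(markers$top_markers$gene_id)
  grns_t <- stage("state_grn_targets", purrr::map(seq_len(K), function(k)
    state_grn(Xall, model$labels, k, target_set,
              keep_fraction = config$keep_fraction_grn,
              max_weight_norm = config$max_weight_norm,
              n_bins = config$n_bins)))
  grns_m <- stage("state_grn_markers", purrr::map(seq_len(K), function(k)
    state_grn(Xall, model$labels, k, marker_set,
              keep_fraction = config$keep_fraction_grn,
              max_weight_norm = config$max_weight_norm,
              n_bins = config$n_bins)))
  e12 <- stage("target_expression_links", target_expression_links(
    Xall, model$labels, target_set, K = K,
    keep_fraction = config$keep_fraction_expr))
  e23 <- stage("target_marker_links", target_marker_links(
    Xall, model$labels, target_set, marker_set, K = K,
    keep_fraction = config$keep_fraction_cross, n_bins = config$n_bins))
  state_order <- order(vapply(seq_len(K), function(k)
    mean(pt[model$labels == k]), numeric(1)))
  ml <- stage("assemble_multilayer", assemble_multilayer(
    cs, grns_t, grns_m, e12, e23,
    signaling_threshold = config$signaling_threshold,
    state_order = state_order))

  manifest <- list(
    parameters = unclass(config),
    n_cells_input = nrow(X), n_cells_retained = nrow(Xf),
    n_genes_input = ncol(X), n_genes_selected = nrow(sel),
    K = K, trajectory = path, start_cluster = start,
    n_transition_cells = nrow(tcs),
    n_multilayer_edges = nrow(ml$edges)
  )

  res <- list(selection = sel, similarity = S, model = model, tcs = tcs,
              W = W, terminals = terminals, path = path, pseudotime = pt,
              markers = markers, signaling = cs, centrality = centr,
              state_grns = grns_t, marker_grns = grns_m, multilayer = ml,
              manifest = manifest)
  if (!is.null(outdir)) write_pipeline_artifacts(res, outdir)
  invisible(res)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_pipeline_artifacts <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write_tsv_plain(res$selection, p("gene_selection.tsv"))
  soft <- data.frame(cell_id = rownames(res$model$H), res$model$H,
                     label = res$model$labels, cpi = res$model$cpi,
                     pseudotime = res$pseudotime, check.names = FALSE)
  colnames(soft)[1 + seq_len(res$model$K)] <- sprintf("H%d", seq_len(res$model$K))
  write_tsv_plain(soft, p("soft_assignment.tsv"))
  write_tsv_plain(res$tcs, p("transition_cells.tsv"))
  cg <- which(upper.tri(res$W), arr.ind = TRUE)
  write_tsv_plain(
    data.frame(u = cg[, 1], v = cg[, 2], tc_fraction = res$W[cg]),
    p("cluster_graph.tsv"))
  jsonlite::write_json(
    list(path = res$path, start = res$path[1],
         terminal_candidates = res$terminals),
    p("trajectory.json"), auto_unbox = FALSE, pretty = TRUE)
  write_tsv_plain(tidy(res$signaling), p("cluster_signaling.tsv"))
  write_tsv_plain(res$centrality, p("centrality.tsv"))
  grn_tbl <- dplyr::bind_rows(
    purrr::imap(res$state_grns, function(g, k)
      dplyr::mutate(as_tibble(g), state = k, layer = "target")),
    purrr::imap(res$marker_grns, function(g, k)
      dplyr::mutate(as_tibble(g), state = k, layer = "marker"))
  )
  write_tsv_plain(grn_tbl, p("state_grns.tsv"))
  jsonlite::write_json(
    list(nodes = as.data.frame(res$multilayer$nodes),
         edges = as.data.frame(res$multilayer$edges),
         state_order = res$multilayer$state_order,
         signaling_threshold = res$multilayer$signaling_threshold),
    p("multilayer.json"), pretty = TRUE, auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Artifact files written by [run_emt_pipeline()]
#' @return Character vector of the file names emitted into `outdir`.
#' @export
pipeline_artifacts <- function() {
  c("manifest.json", "gene_selection.tsv", "soft_assignment.tsv",
    "transition_cells.tsv", "cluster_graph.tsv", "trajectory.json",
    "cluster_signaling.tsv", "centrality.tsv", "state_grns.tsv",
    "multilayer.json")
}
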