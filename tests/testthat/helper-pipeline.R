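# Shared end-to-end helper: generate a synthetic dataset and run the
# clustering + trajectory stages, returning everything recovery tests need.
recover_clustering <- function(seed, sync_mode = "synchronous", config = NULL) {
  cfg <- config %||% synth_config(seed = seed, sync_mode = sync_mode)
  ds <- generate_emt_dataset(cfg)
  sel <- select_genes(ds$expression, 3000)
  Xl <- log_transform(ds$expression[, sel$gene_id])
  S <- consensus_similarity(Xl, seed = seed)
  K <- estimate_num_clusters(S, k_max = min(8L, nrow(S) - 1L))
  H <- suppressWarnings(soft_cluster(S, K, seed = seed))
  model <- cluster_model(H)
  tcs <- identify_transition_cells(model)
  W <- cluster_transition_weights(tcs)
  path <- infer_trajectory(W, select_terminal_states(W)[1])
  pt <- compute_pseudotime(model$H, path)
  map <- match_labels(model$labels, ds$true_labels)
  mapped <- map[path]
  path_recovered <- !any(is.na(mapped)) &&
    (all(mapped == ds$true_path) || all(rev(mapped) == ds$true_path))
  list(dataset = ds, model = model, K = K, tcs = tcs, W = W, path = path,
       pseudotime = pt, map = map, path_recovered = path_recovered,
       ari = mclust::adjustedRandIndex(model$labels, ds$true_labels))
}

# Planted-signal inference on the true labels (isolates the comm module).
recover_signaling <- function(seed) {
  ds <- generate_emt_dataset(synth_config(seed = seed))
  Xl <- log_transform(ds$expression)
  mats <- lapply(seq_len(nrow(ds$pathway$pairs)), function(i)
    lr_signaling_probability(Xl, ds$pathway$pairs$ligand[i],
                             ds$pathway$pairs$receptor[i],
                             ds$pathway$targets_up, ds$pathway$targets_down))
  cs <- cluster_signaling(consensus_signaling(mats), ds$true_labels,
                          ds$config$n_clusters)
  am <- which(cs$Pc == max(cs$Pc), arr.ind = TRUE)[1, ]
  list(cs = cs, hit = all(am == c(ds$planted_signaling$sender[1],
                                  ds$planted_signaling$receiver[1])))
}
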