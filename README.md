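# emtnet

Multiscale analysis of epithelial–mesenchymal transition (EMT) from
single-cell RNA-seq data, for computational biologists studying cell-state
transitions, intermediate cell states and cell–cell communication.

Starting from a cells × genes expression matrix, `emtnet` reconstructs, in
one coherent pipeline:

* **Cell states and transition cells.** Consensus similarity (PCA + k-means
  over a parameter grid) is factorized by symmetric NMF, `S ≈ H Hᵀ`, giving
  each cell a probability vector over `K` states; `K` is chosen by the
  largest gap in the sorted eigenvalues of the symmetric normalized graph
  Laplacian. The **cell plasticity index** `CPI_i = −Σ_k H_ik ln H_ik / ln K`
  flags transition cells (TCs) caught between two states.
* **Trajectory and pseudotime.** TC counts between state pairs define a
  cluster graph; the trajectory is the maximum-weight Hamiltonian path from
  a terminal (E/M) candidate, and pseudotime is the membership-weighted path
  position.
* **Cell–cell communication.** For each ligand–receptor pair, the
  probability that cell *i* signals cell *j* is
  `P_ij ∝ exp(−1/(ℓ_i r_j)) · exp(−1/ū_j) · exp(−d̄_j)` (ligand–receptor
  co-expression, up-target activation, down-target suppression), row
  normalized and averaged over pairs, then aggregated to the directed
  state-level network `P_uv = Σ_{i∈C_u, j∈C_v} P_ij / (|C_u||C_v|)`.
* **State-specific GRNs by partial information decomposition.** For genes
  X, Y the proportional unique contribution
  `U_XY = Σ_Z [U_Z(X→Y) + U_Z(Y→X)] / I(X;Y)` (Williams–Beer `I_min`
  redundancy) is turned into an edge confidence
  `c = F_X(U_XY) + F_Y(U_XY)` through per-gene empirical CDFs; the top 30%
  of edges per state are kept, weights normalized to a maximum of 2.
* **Multilayer network and centrality.** Communication (layer 1), target
  GRNs (layer 2) and marker GRNs (layer 3) replicated over state layers,
  plus state→target and target→marker inter-layer links; strength,
  normalized closeness (cost semantics) and PageRank rank states as
  senders, receivers and signaling hubs.

A synthetic single-cell generator with planted states, transition cells,
trajectory, time-point synchrony and sender→receiver signaling provides
ground truth for every stage.

## Worked example

```r
library(emtnet)

ds <- generate_emt_dataset(synth_config(seed = 1))   # 4 states, 200 cells
sel <- select_genes(ds$expression)                   # bimodal gene selection
Xl  <- log_transform(ds$expression[, sel$gene_id])

S     <- consensus_similarity(Xl, seed = 1)
K     <- estimate_num_clusters(S)                    # -> 4
model <- cluster_model(soft_cluster(S, K, seed = 1))
model
#> <emt_cluster_model> 200 cells, K = 4, mean CPI 0.214

tcs  <- identify_transition_cells(model)             # top 20% CPI
W    <- cluster_transition_weights(tcs)
path <- infer_trajectory(W, select_terminal_states(W)[1])
path
#> [1] 4 2 1 3
match_labels(model$labels, ds$true_labels)[path]     # in planted coordinates
#> [1] 4 3 2 1                                        # planted path, reversed

Xall <- log_transform(ds$expression)                 # no gene filtering here
mats <- lapply(1:2, function(i) lr_signaling_probability(Xall,
  ds$pathway$pairs$ligand[i], ds$pathway$pairs$receptor[i],
  ds$pathway$targets_up, ds$pathway$targets_down))
cs <- cluster_signaling(consensus_signaling(mats), model$labels, K)
signaling_centrality(cs)
#> # A tibble: 4 × 6
#>   state in_strength out_strength in_closeness out_closeness pagerank
#>   <int>       <dbl>        <dbl>        <dbl>         <dbl>    <dbl>
#> 1     1  0.00000286      0.00421     1180288.         1440.   0.0376
#> 2     2  0.000194        0.00204       46298.         1478.   0.0427
#> 3     3  0.00000621      0.0176      2438040.         1436.   0.0376
#> 4     4  0.0252          0.00152         488.       315087.   0.882
```

Reading the numbers: the eigen-gap recovers the four planted states and the
trajectory comes back as the planted path (up to direction, which the
caller fixes with epithelial/mesenchymal markers). State 4 — the planted
signaling receiver — shows the receiver signature: by far the largest
in-strength (0.0252), the *lowest* in-closeness (488; with probabilities as
path costs, strong incoming edges push a receiver far from the rest), and a
PageRank of 0.88, marking it as the signaling hub. State 3 (the planted
sender in these labels) has the largest out-strength.

`run_emt_pipeline()` chains all stages, writes every artifact
(`soft_assignment.tsv`, `trajectory.json`, `cluster_signaling.tsv`,
`state_grns.tsv`, `multilayer.json`, `centrality.tsv`, …) plus a parameter
manifest to an output directory, and is byte-reproducible for a fixed
configuration and seed. `tidy()`/`glance()` methods and
`plot_cpi()`/`plot_cluster_graph()`/`plot_centrality()`/`autoplot()` cover
the result types.

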