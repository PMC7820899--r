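test_that("transition-cell selection honours both selector modes and the top-2 pair rule", {
  H <- rbind(diag(4)[c(1, 2, 3, 4), ],
             c(0.5, 0.4, 0.1, 0),
             c(0.1, 0.45, 0.45, 0))
  m <- cluster_model(H)

  mixed <- identify_transition_cells(m, cpi_threshold = 0.5)
  expect_equal(nrow(mixed), 2) # only the two mixed-membership rows clear 0.5
  tcs <- identify_transition_cells(m, top_fraction = 2 / 6)
  expect_equal(nrow(tcs), 2)
  expect_equal(tcs$cluster_a, c(1, 2))
  expect_equal(tcs$cluster_b, c(2, 3))

  onehot <- cluster_model(diag(4))
  expect_equal(nrow(identify_transition_cells(onehot, cpi_threshold = 0.5)), 0)

  expect_error(identify_transition_cells(m, cpi_threshold = 0.3,
                                         top_fraction = 0.2), "exactly one")
})

test_that("top-fraction selection at the planted rate recovers exactly the planted TCs", {
  ds <- generate_emt_dataset(synth_config(seed = 6))
  m <- cluster_model(ds$true_membership)
  expect_gt(min(m$cpi[ds$is_tc]), max(m$cpi[!ds$is_tc]))
  tcs <- identify_transition_cells(m, top_fraction = ds$config$tc_fraction)
  expect_setequal(tcs$cell, which(ds$is_tc))
})

test_that("transition weights count TC pairs relative to all cells", {
  H <- rbind(diag(4)[rep(1:4, length.out = 90), ],
             matrix(rep(c(0.55, 0.45, 0, 0), 10), 10, 4, byrow = TRUE))
  m <- cluster_model(H)
  tcs <- identify_transition_cells(m, cpi_threshold = 0.3)
  expect_equal(nrow(tcs), 10)
  W <- cluster_transition_weights(tcs, n_total = 100, K = 4)
  expect_equal(W[1, 2], 0.10)
  expect_equal(W, t(W))
  expect_equal(sum(W[upper.tri(W)]), nrow(tcs) / 100)

  empty <- identify_transition_cells(cluster_model(diag(4)), cpi_threshold = 0.9)
  expect_equal(cluster_transition_weights(empty, 4, 4), matrix(0, 4, 4))
})

test_that("terminal-state ranking prefers clusters with least TC involvement", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.1
  W[2, 3] <- W[3, 2] <- 0.1
  W[3, 4] <- W[4, 3] <- 0.1
  r <- select_terminal_states(W)
  expect_setequal(r[1:2], c(1, 4))
  expect_equal(select_terminal_states(matrix(0.2, 3, 3)), 1:3)
})

test_that("trajectory search maximizes path weight with deterministic tie-breaking", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.2
  W[2, 3] <- W[3, 2] <- 0.15
  W[3, 4] <- W[4, 3] <- 0.1
  expect_equal(infer_trajectory(W, 1), c(1, 2, 3, 4))

  expect_equal(infer_trajectory(matrix(0.3, 3, 3), 1), c(1, 2, 3))
  expect_error(infer_trajectory(matrix(0, 11, 11), 1), "10")
})

test_that("trajectory search agrees with an independent exhaustive oracle", {
  for (s in 1:10) {
    K <- sample(3:6, 1)
    W <- withr::with_seed(s, {
      A <- matrix(runif(K * K), K, K); A <- (A + t(A)) / 2; diag(A) <- 0; A
    })
    start <- ((s - 1) %% K) + 1
    expect_equal(infer_trajectory(W, start), best_path_bruteforce(W, start))
  }
})

test_that("pseudotime is the membership-weighted path position", {
  H <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1), c(0.5, 0.5, 0, 0))
  pt <- compute_pseudotime(H, path = 1:4)
  expect_equal(pt, c(0, 1, 0.5 / 3))
  # reversing the path reflects pseudotime
  expect_equal(compute_pseudotime(H, path = 4:1), 1 - pt)
  expect_error(compute_pseudotime(H, path = c(1, 2, 3)), "permutation")
})

test_that("marker inference scores exclusive genes 1 and flat genes uniformly", {
  H <- rbind(diag(3), diag(3), diag(3))
  X <- cbind(excl = rep(c(2, 0, 0), 3), flat = rep(1.5, 9))
  rownames(X) <- sprintf("c%d", 1:9)
  mt <- infer_marker_genes(X, H, top_m = 2)
  expect_equal(unname(mt$scores["excl", ]), c(1, 0, 0))
  expect_equal(unname(mt$scores["flat", ]), rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(nrow(mt$top_markers), 6)
})

test_that("planted markers are recovered as their cluster's top markers without noise", {
  cfg <- synth_config(seed = 8, tc_fraction = 0, dropout_rate = 0,
                      dispersion = 0, mean_low = 0, cells_per_cluster = 15,
                      n_genes = 120, markers_per_cluster = 5)
  ds <- generate_emt_dataset(cfg)
  Xl <- log_transform(ds$expression)
  mt <- infer_marker_genes(Xl, ds$true_membership, top_m = 5)
  for (k in 1:4) {
    # planted markers are exactly cluster-exclusive: NNLS score 1 for their
    # own state, 0 elsewhere
    own <- sprintf("M%d_%d", k, 1:5)
    expect_equal(unname(mt$scores[own, k]), rep(1, 5))
    expect_true(all(mt$scores[own, -k] == 0))
    # every reported top marker is an exclusively-k gene (pathway genes
    # planted in state k tie with the markers at score 1)
    top <- mt$top_markers$gene_id[mt$top_markers$cluster == k]
    expect_true(all(mt$scores[top, k] == 1))
  }
})

test_that("transition genes rank pseudotime-tracking genes first and constants last", {
  w <- seq(0.95, 0.05, length.out = 15) # strictly increasing pseudotime
  H <- rbind(cbind(w, 1 - w, 0, 0),
             matrix(rep(c(0, 0, 0.2, 0.8), 2), 2, 4, byrow = TRUE))
  colnames(H) <- NULL
  pt <- compute_pseudotime(H, 1:4)
  X <- cbind(ramp = seq_len(17), noise = rep(c(1, 3, 2, 5), length.out = 17),
             const = rep(2, 17))
  rownames(X) <- sprintf("c%d", 1:17)
  tg <- infer_transition_genes(X, H, pt, pair = c(1, 2))
  expect_equal(tg$gene_id[1], "ramp")
  expect_equal(tg$score[1], 1)
  expect_equal(tg$score[tg$gene_id == "const"], 0)
  expect_equal(tg$gene_id[3], "const")
  expect_error(infer_transition_genes(X, H, pt, pair = c(3, 4)), "fewer than 3")
})
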