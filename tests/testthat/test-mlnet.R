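expr_fixture <- function() {
  X <- rbind(c(2, 0, 1, 4),
             c(4, 0, 1, 4),
             c(0, 3, 1, 0),
             c(0, 5, 1, 0))
  dimnames(X) <- list(sprintf("c%d", 1:4), c("t1", "t2", "m1", "m2"))
  X
}

test_that("state-to-target links are per-state mean expression with global pruning", {
  X <- expr_fixture()
  labels <- c(1, 1, 2, 2)
  all_links <- target_expression_links(X, labels, c("t1", "t2"),
                                       keep_fraction = 0.999)
  expect_equal(nrow(all_links), 4)
  expect_equal(all_links$weight[all_links$state == 1 & all_links$gene == "t1"], 3)
  expect_equal(all_links$weight[all_links$state == 2 & all_links$gene == "t2"], 4)
  expect_equal(all_links$weight[all_links$state == 2 & all_links$gene == "t1"], 0)

  pruned <- target_expression_links(X, labels, c("t1", "t2"), K = 5,
                                    keep_fraction = 0.2)
  expect_equal(nrow(pruned), ceiling(0.2 * 5 * 2)) # 10 candidates -> 2 kept
  expect_error(target_expression_links(X, labels, character()), "non-empty")
})

test_that("target-marker cross links retain only cross pairs and obey the global cap", {
  X <- withr::with_seed(2, {
    m <- matrix(rpois(40 * 5, 6) + 0, 40, 5)
    dimnames(m) <- list(sprintf("c%d", 1:40), c("t1", "t2", "m1", "m2", "m3"))
    m
  })
  labels <- rep(1:2, each = 20)
  full <- target_marker_links(X, labels, c("t1", "t2"), c("m1", "m2", "m3"),
                              keep_fraction = 1)
  expect_equal(nrow(full), 2 * 2 * 3) # every cross pair in both states
  expect_true(all(full$target %in% c("t1", "t2")))
  expect_true(all(full$marker %in% c("m1", "m2", "m3")))

  capped <- target_marker_links(X, labels, c("t1", "t2"), c("m1", "m2", "m3"),
                                keep_fraction = 0.25)
  expect_equal(nrow(capped), ceiling(0.25 * 2 * 2 * 3))
})

test_that("multilayer assembly thresholds layer 1 and counts node-layer tuples", {
  X <- withr::with_seed(3, {
    m <- matrix(rpois(40 * 5, 6) + 0, 40, 5)
    dimnames(m) <- list(sprintf("c%d", 1:40), c("t1", "t2", "t3", "m1", "m2"))
    m
  })
  labels <- rep(1:2, each = 20)
  targets <- c("t1", "t2", "t3"); markers <- c("m1", "m2")
  tg <- lapply(1:2, function(k) state_grn(X, labels, k, targets, keep_fraction = 0.5))
  mg <- lapply(1:2, function(k) state_grn(X, labels, k, c(markers, "t1"),
                                          keep_fraction = 0.5))
  e12 <- target_expression_links(X, labels, targets, keep_fraction = 0.5)
  e23 <- target_marker_links(X, labels, targets, markers, keep_fraction = 0.5)
  Pc <- matrix(c(0, 0.6, 0.4, 0), 2, 2, byrow = TRUE)

  ml <- assemble_multilayer(Pc, tg, mg, e12, e23, signaling_threshold = 0.5)
  expect_s3_class(ml, "emt_multilayer")
  expect_equal(sum(ml$edges$kind == "intra1"), 1)
  T_set <- length(ml$targets); A_set <- length(ml$markers)
  expect_equal(nrow(ml$nodes), 2 * (1 + T_set + A_set))

  # raising the threshold never adds layer-1 edges
  ml7 <- assemble_multilayer(Pc, tg, mg, e12, e23, signaling_threshold = 0.7)
  expect_lte(sum(ml7$edges$kind == "intra1"), sum(ml$edges$kind == "intra1"))

  g <- glance(ml)
  expect_equal(g$n_states, 2)
  expect_equal(nrow(tidy(ml)), nrow(ml$edges))

  # mismatched state sets are rejected
  expect_error(assemble_multilayer(Pc, tg[1], mg[1], e12, e23), "per state")
})

test_that("empty GRNs still assemble into a valid multilayer network", {
  Pc <- matrix(c(0, 0.8, 0, 0), 2, 2, byrow = TRUE)
  empty_grn <- function(genes) {
    g <- tibble::tibble(gene_x = character(), gene_y = character(),
                        weight = numeric())
    structure(g, class = c("emt_state_grn", class(g)), genes = genes)
  }
  tg <- lapply(1:2, function(k) empty_grn(c("t1", "t2")))
  mg <- lapply(1:2, function(k) empty_grn(c("m1", "m2")))
  links0 <- tibble::tibble(state = integer(), gene = character(),
                           weight = numeric())
  cross0 <- tibble::tibble(state = integer(), target = character(),
                           marker = character(), weight = numeric())
  ml <- assemble_multilayer(Pc, tg, mg, links0, cross0)
  expect_equal(sum(ml$edges$kind %in% c("intra2", "intra3")), 0)
  expect_equal(nrow(ml$nodes), 2 * (1 + 2 + 2))
})

test_that("strength sums directed edge weights with mass conservation", {
  M <- matrix(0, 2, 2); M[1, 2] <- 0.3
  expect_equal(unname(node_strength(M, "in")), c(0, 0.3))
  expect_equal(unname(node_strength(M, "out")), c(0.3, 0))

  M3 <- withr::with_seed(5, matrix(runif(9), 3, 3))
  expect_equal(sum(node_strength(M3, "in")), sum(M3))
  expect_equal(sum(node_strength(M3, "in")), sum(node_strength(M3, "out")))
  expect_equal(unname(node_strength(M3, "in")), colSums(M3))
})

test_that("closeness reproduces the two-node worked example and complete-graph symmetry", {
  M <- matrix(0, 2, 2); M[1, 2] <- 0.5
  expect_equal(unname(node_closeness(M, "out")), c(2, 0))
  expect_equal(unname(node_closeness(M, "in")), c(0, 2))

  Mc <- matrix(1, 4, 4); diag(Mc) <- 0
  expect_equal(unname(node_closeness(Mc, "in")), rep(1, 4))
  expect_equal(unname(node_closeness(Mc, "out")), rep(1, 4))
})

test_that("closeness matches a brute-force Dijkstra oracle on random digraphs", {
  for (s in 1:15) {
    M <- withr::with_seed(100 + s, {
      A <- matrix(runif(36, 0.1, 1), 6, 6)
      A[sample(36, 20)] <- 0
      diag(A) <- 0
      A
    })
    expect_equal(unname(node_closeness(M, "out")), closeness_bruteforce(M, "out"),
                 tolerance = 1e-9)
    expect_equal(unname(node_closeness(M, "in")), closeness_bruteforce(M, "in"),
                 tolerance = 1e-9)
  }
})

test_that("pagerank matches the dense Google-matrix eigenvector and igraph", {
  M2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(unname(node_pagerank(M2)), c(0.5, 0.5))

  for (s in 1:15) {
    M <- withr::with_seed(200 + s, {
      A <- matrix(runif(25), 5, 5)
      A[sample(25, 10)] <- 0
      diag(A) <- 0
      A
    })
    pr <- unname(node_pagerank(M))
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_equal(pr, pagerank_bruteforce(M), tolerance = 1e-9)
    g <- igraph::graph_from_adjacency_matrix(M, mode = "directed", weighted = TRUE)
    expect_equal(pr, igraph::page_rank(g, damping = 0.85)$vector,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("a pure receiver shows maximal in-strength and the lowest in-closeness", {
  # three interconnected senders (weak edges) all signaling into state 4
  M <- matrix(0, 4, 4)
  M[1:3, 1:3] <- 0.1; diag(M) <- 0
  M[1:3, 4] <- 0.9
  s_in <- node_strength(M, "in")
  expect_equal(unname(which.max(s_in)), 4)
  cl_in <- node_closeness(M, "in")
  expect_gt(cl_in[4], 0)
  expect_true(all(cl_in[4] < cl_in[1:3]))
})

test_that("the centrality table aggregates all five metrics", {
  M <- withr::with_seed(6, matrix(runif(16), 4, 4))
  diag(M) <- 0
  tab <- signaling_centrality(M)
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("state", "in_strength", "out_strength",
                      "in_closeness", "out_closeness", "pagerank"))
  expect_equal(sum(tab$pagerank), 1, tolerance = 1e-9)
})
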