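fair2 <- c(0, 0, 1, 1)
fair2b <- c(0, 1, 0, 1)

test_that("uniform-width discretization handles constants, exact edges and the Sturges rule", {
  X <- cbind(const = rep(2, 4), four = c(0, 1, 2, 3))
  D <- discretize_matrix(X, n_bins = 2)
  expect_equal(D$n_bins, c(1L, 2L))
  expect_equal(unname(D$codes[, "const"]), rep(0L, 4))
  expect_equal(unname(D$codes[, "four"]), c(0L, 0L, 1L, 1L))

  D8 <- discretize_matrix(matrix(1:8, 8, 1))
  expect_equal(D8$n_bins, 4L) # ceiling(log2(8) + 1)
  expect_identical(discretize_matrix(X), discretize_matrix(X))
})

test_that("mutual information matches hand-evaluated joints and the table oracle", {
  expect_equal(mutual_information(fair2, fair2), 1)
  expect_equal(mutual_information(rep(0, 6), rep(1, 6)), 0)

  # joint p(0,0)=p(1,1)=3/8, p(0,1)=p(1,0)=1/8 as an 8-sample dataset
  x <- c(0, 0, 0, 0, 1, 1, 1, 1)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  expect_equal(mutual_information(x, y), 1 + 0.25 * log2(0.25) + 0.75 * log2(0.75),
               tolerance = 1e-12)

  for (s in 1:25) {
    xy <- withr::with_seed(s, list(x = sample(0:3, 30, TRUE),
                                   y = sample(0:2, 30, TRUE)))
    expect_equal(mutual_information(xy$x, xy$y), mi_bruteforce(xy$x, xy$y),
                 tolerance = 1e-12)
    expect_equal(mutual_information(xy$x, xy$y), mutual_information(xy$y, xy$x))
  }
})

test_that("Williams-Beer redundancy reproduces the logic-gate closed forms", {
  # perfect copies: every source carries the full bit
  expect_equal(redundancy_imin(fair2, fair2, fair2), 1)
  # XOR: neither source alone carries specific information
  y_xor <- as.integer(xor(fair2, fair2b))
  expect_equal(redundancy_imin(y_xor, fair2, fair2b), 0)
  # a constant source pins the minimum at zero
  expect_equal(redundancy_imin(fair2, fair2, rep(0, 4)), 0)
})

test_that("unique information matches the decomposition identities", {
  x8 <- rep(fair2, 2); z8 <- rep(fair2b, 2)
  expect_equal(unique_information(x8, x8, z8), 1) # Y = X, Z independent
  expect_equal(unique_information(fair2, fair2, fair2), 0) # Y = X = Z
  y_xor <- as.integer(xor(fair2, fair2b))
  expect_equal(unique_information(fair2, y_xor, fair2b), 0)
})

test_that("PID inequalities hold over exhaustively enumerated binary triples", {
  configs <- expand.grid(a = 0:7, b = 0:7, c = 0:7)[1:120, ]
  bits <- function(n) as.integer(intToBits(n))[1:3]
  for (r in seq_len(nrow(configs))) {
    x <- bits(configs$a[r]); z <- bits(configs$b[r]); y <- bits(configs$c[r])
    imin <- redundancy_imin(y, x, z)
    expect_gte(imin, 0)
    expect_lte(imin, min(mutual_information(x, y), mutual_information(z, y)) + 1e-12)
    expect_gte(unique_information(x, y, z), 0)
  }
})

test_that("PUC matrix reproduces the three-gene closed forms", {
  x8 <- rep(fair2, 2); z8 <- rep(fair2b, 2)
  # all three genes identical: everything is redundant
  U0 <- puc_matrix(cbind(a = fair2, b = fair2, c = fair2))
  expect_true(all(U0 == 0))
  # X = Y fair with independent Z: both directional uniques are 1 bit
  U2 <- puc_matrix(cbind(a = x8, b = x8, c = z8))
  expect_equal(U2["a", "b"], 2)
  expect_equal(U2["a", "c"], 0) # I(a; c) = 0 convention

  Ur <- puc_matrix(withr::with_seed(9, matrix(sample(0:2, 60, TRUE), 20, 3)))
  expect_equal(Ur, t(Ur))
  expect_true(all(diag(Ur) == 0) && all(Ur >= 0))
  expect_error(puc_matrix(cbind(fair2, fair2)), "3 genes")
})

test_that("edge confidence reproduces the ECDF worked example", {
  U <- matrix(c(0, 2, 1,
                2, 0, 0,
                1, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  C <- confidence_network(U)
  expect_equal(C["A", "B"], 2.0)
  expect_equal(C["A", "C"], 1.5)
  expect_equal(C["B", "C"], 1.0)

  Uc <- matrix(1, 4, 4); diag(Uc) <- 0
  Cc <- confidence_network(Uc)
  expect_true(all(Cc[upper.tri(Cc)] == 2))
})

test_that("confidence is invariant under monotone rescaling and stays within (0, 2]", {
  U <- withr::with_seed(12, {
    A <- matrix(runif(36), 6, 6); A <- (A + t(A)) / 2; diag(A) <- 0; A
  })
  C <- confidence_network(U)
  expect_equal(C, t(C))
  expect_true(all(C[upper.tri(C)] > 0 & C[upper.tri(C)] <= 2))
  # strictly monotone transform of all scores preserves every ECDF rank
  expect_equal(confidence_network(U^3), C)
  expect_equal(confidence_network(2 * U + 0), C)
})

test_that("state GRN pruning and normalization follow the ceiling and max-2 rules", {
  X <- withr::with_seed(7, {
    m <- matrix(rpois(12 * 5, 5), 12, 5)
    dimnames(m) <- list(sprintf("c%d", 1:12), sprintf("g%d", 1:5))
    m + 0
  })
  labels <- rep(1L, 12)
  g <- state_grn(X, labels, state = 1, genes = colnames(X),
                 keep_fraction = 0.3, max_weight_norm = 2)
  expect_equal(nrow(g), ceiling(0.3 * 10)) # 10 candidate edges -> 3 kept
  expect_equal(max(g$weight), 2)
  expect_true(all(diff(g$weight) <= 0))

  expect_error(state_grn(X, labels, state = 2, genes = colnames(X)), "state 2")
  expect_error(state_grn(X, labels, state = 1, genes = c("g1", "g2")), "3 genes")
})

test_that("a planted co-regulated pair outranks independent pairs in confidence", {
  wins <- vapply(1:20, function(s) {
    X <- withr::with_seed(s, {
      base <- rpois(40, 8)
      cbind(a = base + rpois(40, 1),
            b = base + rpois(40, 1),
            c = rpois(40, 8), d = rpois(40, 8), e = rpois(40, 8))
    })
    rownames(X) <- sprintf("c%d", 1:40)
    g <- state_grn(X + 0, rep(1L, 40), 1, colnames(X), keep_fraction = 0.999)
    g$gene_x[1] == "a" && g$gene_y[1] == "b"
  }, logical(1))
  expect_gte(mean(wins), 0.75)
})
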