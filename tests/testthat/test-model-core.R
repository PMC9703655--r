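test_that("embedding and dense layers match hand-computed values", {
  relu <- function(x) pmax(x, 0)
  # dense embedding worked example
  expect_equal(dense_embedding_forward(c(1, 2),
                                       matrix(c(1, 1, 0, 1), 2, 2),
                                       c(0.5, -10)),
               c(3.5, 0))
  expect_equal(dense_embedding_forward(c(1, 2), matrix(0, 2, 3),
                                       numeric(3)), c(0, 0, 0))
  expect_equal(dense_embedding_forward(c(1, -2), diag(2), c(0, 0),
                                       f = identity), c(1, -2))
  # graph embedding worked example
  A <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  expect_equal(graph_embedding_forward(c(1, 2, 3), matrix(1, 3, 3), A,
                                       numeric(3), f = identity),
               c(3, 3, 3))
  # dense layer worked example
  expect_equal(dense_layer_forward(c(1, -1), matrix(c(2, 0, 0, 2), 2, 2),
                                   c(0, 1)), c(2, 0))
  expect_equal(dense_layer_forward(c(1, 2), matrix(0, 2, 2), c(3, -1)),
               c(3, 0))
  expect_error(dense_embedding_forward(c(1, 2, 3), diag(2), c(0, 0)),
               "dimension mismatch")
  expect_error(graph_embedding_forward(c(1, 2), diag(2), diag(3),
                                       c(0, 0)), "dimension mismatch")
})

test_that("layer forwards match explicit-loop oracles on random instances", {
  set.seed(101)
  for (rep in 1:100) {
    n_in <- sample(2:8, 1); n_out <- sample(2:8, 1)
    x <- rnorm(n_in); W <- matrix(rnorm(n_in * n_out), n_in, n_out)
    b <- rnorm(n_out)
    expect_equal(dense_embedding_forward(x, W, b),
                 oracle_dense_forward(x, W, b, relu_s), tolerance = 1e-12)
    Wsq <- matrix(rnorm(n_in * n_in), n_in, n_in)
    A <- matrix(rbinom(n_in * n_in, 1, 0.5), n_in, n_in)
    A <- 1 * ((A + t(A) + diag(n_in)) > 0)
    bs <- rnorm(n_in)
    expect_equal(graph_embedding_forward(x, Wsq, A, bs),
                 oracle_graph_forward(x, Wsq, A, bs, relu_s),
                 tolerance = 1e-12)
  }
})

test_that("all-ones adjacency makes graph embedding equal dense embedding", {
  set.seed(77)
  for (rep in 1:1000) {
    n <- sample(2:20, 1)
    x <- rnorm(n); W <- matrix(rnorm(n * n), n, n); b <- rnorm(n)
    expect_equal(graph_embedding_forward(x, W, matrix(1, n, n), b),
                 dense_embedding_forward(x, W, b), tolerance = 1e-14)
  }
})

test_that("each graph-embedding unit sees only adjacency-permitted inputs", {
  set.seed(78)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    W <- matrix(rnorm(n * n), n, n)
    A <- matrix(rbinom(n * n, 1, 0.4), n, n)
    A <- 1 * ((A + t(A) + diag(n)) > 0)
    b <- rnorm(n)
    x <- rnorm(n)
    base <- graph_embedding_forward(x, W, A, b, f = identity)
    for (i in seq_len(n)) {           # exhaustive input perturbation
      xp <- x; xp[i] <- xp[i] + 1
      delta <- graph_embedding_forward(xp, W, A, b, f = identity) - base
      expect_true(all(abs(delta[A[i, ] == 0]) == 0))
    }
  }
  # single-column identity adjacency: only unit j responds
  A <- diag(3)
  W <- matrix(rnorm(9), 3, 3)
  x <- rnorm(3)
  for (j in 1:3) {
    xp <- x; xp[j] <- xp[j] + 2
    delta <- graph_embedding_forward(xp, W, A, numeric(3), f = identity) -
      graph_embedding_forward(x, W, A, numeric(3), f = identity)
    expect_true(all(delta[-j] == 0))
  }
})

test_that("attention normalization satisfies the kill-matrix identity", {
  # uniform raw weights: 1/M on the diagonal, 0 elsewhere
  W <- attention_normalize(array(1.3, dim = c(4, 3, 4)))
  for (d in 1:4) for (i in 1:4)
    expect_equal(sum(W[d, , i]), as.numeric(d == i), tolerance = 1e-15)
  expect_equal(W[2, 1, 2], 1 / 3)
  # M = 1 degenerate
  W1 <- attention_normalize(array(rnorm(5), dim = c(5, 1, 5)))
  expect_equal(diag(W1[, 1, ]), rep(1, 5))
  # worked softmax: ln 3 vs 0 -> 0.75 / 0.25
  W3 <- array(0, dim = c(2, 2, 2))
  W3[1, 1, 1] <- log(3)
  W <- attention_normalize(W3)
  expect_equal(W[1, , 1], c(0.75, 0.25))
  # matches the explicit-loop oracle on random instances
  set.seed(55)
  for (rep in 1:100) {
    n_d <- sample(2:6, 1); M <- sample(1:4, 1)
    W3 <- array(rnorm(n_d * M * n_d, sd = 2), dim = c(n_d, M, n_d))
    expect_equal(attention_normalize(W3), oracle_attention_normalize(W3),
                 tolerance = 1e-12)
  }
  # extreme raw weights stay exactly normalized (stable softmax)
  for (rep in 1:50) {
    W3 <- array(sample(c(-50, 0, 50), 3 * 2 * 3, replace = TRUE),
                dim = c(3, 2, 3))
    W <- attention_normalize(W3)
    for (d in 1:3) for (i in 1:3)
      expect_equal(sum(W[d, , i]), as.numeric(d == i), tolerance = 1e-12)
  }
})

test_that("attention scores reduce to per-drug convex weights", {
  W <- attention_normalize(array(0.4, dim = c(6, 5, 6)))
  s <- attention_scores(W)
  expect_equal(dim(s), c(5L, 6L))
  expect_true(all(abs(s - 0.2) < 1e-15))
  # 0.75/0.25 example
  W3 <- array(0, dim = c(2, 2, 2)); W3[1, 1, 1] <- log(3)
  s <- attention_scores(attention_normalize(W3))
  expect_equal(s[, 1], c(0.75, 0.25))
  # columns sum to 1 across many random draws
  set.seed(66)
  for (rep in 1:1000) {
    W3 <- array(rnorm(3 * 2 * 3, sd = 5), dim = c(3, 2, 3))
    expect_equal(colSums(attention_scores(attention_normalize(W3))),
                 rep(1, 3), tolerance = 1e-12)
  }
  # monotonicity: raising W3[d, m, d] raises score(m, d), lowers the rest
  W3 <- array(rnorm(4 * 3 * 4), dim = c(4, 3, 4))
  s0 <- attention_scores(attention_normalize(W3))
  W3b <- W3; W3b[2, 1, 2] <- W3b[2, 1, 2] + 0.5
  s1 <- attention_scores(attention_normalize(W3b))
  expect_gt(s1[1, 2], s0[1, 2])
  expect_true(all(s1[-1, 2] <= s0[-1, 2]))
  expect_equal(s1[, -2], s0[, -2], tolerance = 1e-15)
})

test_that("fusion is a convex combination of per-omics head predictions", {
  # worked example: weights 0.75/0.25 and 0.5/0.5
  W3 <- array(0, dim = c(2, 2, 2))
  W3[1, 1, 1] <- log(3)
  att <- attention_params(W3, b = c(0, 0))
  y <- fuse_and_predict(list(c(1, 2), c(3, 6)), att)
  expect_equal(y, c(1.5, 4.0))
  # M = 1: output equals the head
  att1 <- init_attention_params(3, 1)
  expect_equal(fuse_and_predict(list(c(1, -2, 0.5)), att1), c(1, -2, 0.5))
  # equal heads are a fixed point regardless of raw weights
  set.seed(8)
  for (rep in 1:20) {
    W3 <- array(rnorm(3 * 4 * 3, sd = 3), dim = c(3, 4, 3))
    b <- rnorm(3)
    v <- rnorm(3)
    att <- attention_params(W3, b)
    expect_equal(fuse_and_predict(rep(list(v), 4), att), v + b,
                 tolerance = 1e-12)
    # convexity bounds per drug with zero bias
    att0 <- attention_params(W3, numeric(3))
    heads <- replicate(4, rnorm(3), simplify = FALSE)
    y <- fuse_and_predict(heads, att0)
    H <- do.call(rbind, heads)
    expect_true(all(y >= apply(H, 2, min) - 1e-12))
    expect_true(all(y <= apply(H, 2, max) + 1e-12))
  }
  expect_error(fuse_and_predict(list(c(1, 2, 3)),
                                attention_params(array(0, c(2, 1, 3)),
                                                 numeric(2))),
               "configuration error")
})

test_that("sub-network forward composes the three layers", {
  # all-zero weights: output is the head bias exactly
  p <- subnetwork_params(W1 = matrix(0, 2, 3), b1 = numeric(3),
                         W2 = matrix(0, 3, 2), b2 = numeric(2),
                         Wh = matrix(0, 2, 4), bh = c(1, -1, 0.5, 2))
  expect_equal(subnetwork_forward(c(5, -3), p), c(1, -1, 0.5, 2))
  # hand-set weights match the composition of the per-layer oracles
  set.seed(12)
  W1 <- matrix(rnorm(4), 2, 2); b1 <- rnorm(2)
  W2 <- matrix(rnorm(6), 2, 3); b2 <- rnorm(3)
  Wh <- matrix(rnorm(6), 3, 2); bh <- rnorm(2)
  p2 <- subnetwork_params(W1, b1, W2, b2, Wh, bh)
  x <- c(0.3, -1.2)
  manual <- oracle_dense_forward(
    oracle_dense_forward(oracle_dense_forward(x, W1, b1, relu_s),
                         W2, b2, relu_s),
    Wh, bh, identity)
  expect_equal(subnetwork_forward(x, p2), manual, tolerance = 1e-12)
  # inference is deterministic even with dropout rates configured
  p3 <- subnetwork_params(W1, b1, W2, b2, Wh, bh,
                          dropout = c(embed = 0.5, hidden = 0.3))
  expect_identical(subnetwork_forward(x, p3), subnetwork_forward(x, p3))
  # graph-embedded params require matching square shapes
  expect_error(subnetwork_params(W1 = matrix(0, 2, 3), b1 = numeric(3),
                                 W2 = matrix(0, 3, 2), b2 = numeric(2),
                                 Wh = matrix(0, 2, 2), bh = numeric(2),
                                 A = diag(2)), "square")
})
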