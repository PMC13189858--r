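test_that("adjacency normalisation matches hand and dense-oracle results", {
  # alpha = beta = 0 leaves the augmented adjacency untouched
  g <- randomSmallGraph(6)
  na0 <- normalizeAdjacency(g, 0, 0)
  expect_equal(as.matrix(ahatMatrix(na0)),
               as.matrix(adjacencyMatrix(g, selfLoops = TRUE)))
  # empty graph with self loops is the identity for any exponents
  ge <- CellGraph(4)
  expect_equal(as.matrix(ahatMatrix(normalizeAdjacency(ge, 0.7, 0.3))),
               diag(4))
  # two-node worked example: single edge 1 -> 2, self loops, a = b = 1/2
  g2 <- CellGraph(2, rbind(c(1L, 2L)), selfLoopsAdded = FALSE)
  expect_equal(as.matrix(ahatMatrix(normalizeAdjacency(g2, 0.5, 0.5))),
               matrix(c(2^-0.5, 0, 2^-1, 2^-0.5), 2, 2),
               tolerance = 1e-12)
  # dense-matrix oracle on random graphs and exponents
  set.seed(21)
  for (rep in 1:10) {
    g <- randomSmallGraph(sample(3:8, 1))
    a <- runif(1); b <- runif(1)
    expect_equal(as.matrix(ahatMatrix(normalizeAdjacency(g, a, b))),
                 bruteAhat(adjacencyMatrix(g), a, b), tolerance = 1e-12)
  }
})

test_that("directed layers match the per-node aggregation oracle", {
  set.seed(22)
  for (rep in 1:100) {
    n <- sample(3:8, 1); dIn <- sample(2:3, 1); dOut <- sample(2:3, 1)
    g <- randomSmallGraph(n)
    Ahat <- normalizeAdjacency(g, runif(1), runif(1))
    S <- matrix(rnorm(n * dIn), n); T <- matrix(rnorm(n * dIn), n)
    WS <- matrix(rnorm(dIn * dOut), dIn); WT <- matrix(rnorm(dIn * dOut), dIn)
    out <- directedLayer(Ahat, S, T, WS, WT)
    expect_equal(out$S,
                 bruteAggregate(ahatMatrix(Ahat), T,
                                rep(list(WT), n)), tolerance = 1e-10)
    expect_equal(out$T,
                 bruteAggregate(Matrix::t(ahatMatrix(Ahat)), S,
                                rep(list(WS), n)), tolerance = 1e-10)
    # heterogeneous layer with two distinct per-type weight sets
    types <- sample(c("a", "b"), n, replace = TRUE)
    WSl <- list(a = matrix(rnorm(dIn * dOut), dIn),
                b = matrix(rnorm(dIn * dOut), dIn))
    WTl <- list(a = matrix(rnorm(dIn * dOut), dIn),
                b = matrix(rnorm(dIn * dOut), dIn))
    outH <- heteroDirectedLayer(Ahat, S, T, types, WSl, WTl)
    expect_equal(outH$S,
                 bruteAggregate(ahatMatrix(Ahat), T, WTl[types]),
                 tolerance = 1e-10)
    expect_equal(outH$T,
                 bruteAggregate(Matrix::t(ahatMatrix(Ahat)), S, WSl[types]),
                 tolerance = 1e-10)
  }
})

test_that("layer identities hold: identity operator swaps channels", {
  n <- 5; d <- 3
  Ahat <- diag(n)
  S <- matrix(rnorm(n * d), n); T <- matrix(rnorm(n * d), n)
  out <- directedLayer(Ahat, S, T, diag(d), diag(d))
  expect_equal(out$S, T)
  expect_equal(out$T, S)
  outZ <- directedLayer(Ahat, S, matrix(0, n, d), diag(d), diag(d))
  expect_equal(outZ$S, matrix(0, n, d))
  # two types sharing one weight matrix reduce to the homogeneous layer
  W1 <- matrix(rnorm(d * d), d); W2 <- matrix(rnorm(d * d), d)
  types <- rep(c("a", "b"), length.out = n)
  expect_equal(
    heteroDirectedLayer(Ahat, S, T, types,
                        list(a = W1, b = W1), list(a = W2, b = W2)),
    directedLayer(Ahat, S, T, W1, W2))
  expect_error(heteroDirectedLayer(Ahat, S, T, c(types[-1], "c"),
                                   list(a = W1, b = W1),
                                   list(a = W2, b = W2)),
               "missing-type")
})

test_that("encoder equals the composition of two directed layers", {
  set.seed(23)
  n <- 5; M <- 7; h <- 4; d <- 2
  g <- randomSmallGraph(n, 0.6)
  Ahat <- normalizeAdjacency(g, 0.5, 0.5)
  X <- matrix(abs(rnorm(n * M)), n)
  ws <- list(WS0 = matrix(rnorm(M * h), M), WT0 = matrix(rnorm(M * h), M),
             WS1 = matrix(rnorm(h * d), h), WT1 = matrix(rnorm(h * d), h))
  enc <- digaeEncode(Ahat, X, X, ws)
  relu <- function(m) pmax(m, 0)
  l1 <- directedLayer(Ahat, X, X, ws$WS0, ws$WT0, activation = relu)
  l2 <- directedLayer(Ahat, l1$S, l1$T, ws$WS1, ws$WT1)
  expect_equal(enc$ZS, l2$S, tolerance = 1e-8)
  expect_equal(enc$ZT, l2$T, tolerance = 1e-8)
  # zero weights give zero codes; identity-shaped limit returns X
  ws0 <- lapply(ws, function(w) w * 0)
  enc0 <- digaeEncode(Ahat, X, X, ws0)
  expect_true(all(enc0$ZS == 0) && all(enc0$ZT == 0))
  wsI <- list(WS0 = diag(M), WT0 = diag(M), WS1 = diag(M), WT1 = diag(M))
  encI <- digaeEncode(diag(n), X, X, wsI)
  expect_equal(encI$ZS, X)  # ReLU(X) = X for non-negative X
})

test_that("decoder is the elementwise logistic of the latent inner product", {
  # sigma(0) = 0.5 grid
  res <- digaeDecode(matrix(0, 3, 2), matrix(rnorm(6), 3, 2))
  expect_true(all(abs(edgeProbabilities(res) - 0.5) < 1e-12))
  # all off-diagonal pairs called at threshold 0.5 (inclusive boundary)
  expect_identical(nrow(predictedEdges(res)), 6L)
  # scalar evaluations
  r2 <- digaeDecode(matrix(c(1, 0), 1, 2),
                    matrix(c(1, -1, 0, 0), 2, 2))
  expect_equal(as.numeric(edgeProbabilities(r2)),
               c(1 / (1 + exp(-1)), 1 / (1 + exp(1))), tolerance = 1e-4)
  # symmetric when ZS = ZT, asymmetric capacity otherwise
  Z <- matrix(rnorm(8), 4, 2)
  expect_equal(edgeProbabilities(digaeDecode(Z, Z)),
               t(edgeProbabilities(digaeDecode(Z, Z))))
  Z2 <- matrix(rnorm(8), 4, 2)
  expect_false(isTRUE(all.equal(edgeProbabilities(digaeDecode(Z, Z2)),
                                t(edgeProbabilities(digaeDecode(Z, Z2))))))
  expect_error(digaeDecode(Z, Z[, 1, drop = FALSE]), "dimension")
})

test_that("reconstruction loss reproduces closed-form values", {
  A <- matrix(0.5, 3, 3)
  pos <- rbind(c(1L, 2L)); neg <- rbind(c(2L, 3L))
  expect_equal(reconstructionLoss(A, pos, neg), log(2), tolerance = 1e-12)
  A2 <- matrix(0, 3, 3); A2[1, 2] <- 1
  expect_lt(reconstructionLoss(A2, pos, neg), 2e-6)  # clip floor
  A3 <- matrix(0, 3, 3); A3[1, 2] <- 0.8; A3[2, 3] <- 0.4
  expect_equal(reconstructionLoss(A3, pos, neg),
               -0.5 * (log(0.8) + log(0.6)), tolerance = 1e-12)
  expect_error(reconstructionLoss(A, pos[0, , drop = FALSE], neg),
               "empty positive")
})

test_that("training is deterministic and learns planted structure", {
  sim <- quickSim(300, 60, seed = 1)
  sp <- splitEdges(sim$graph, 0.1, seed = 1)
  m1 <- trainDigae(sim$dataset, sp, epochs = 60, seed = 4)
  m2 <- trainDigae(sim$dataset, sp, epochs = 60, seed = 4)
  expect_identical(lossTrace(m1), lossTrace(m2))
  expect_identical(latentCodes(m1)$ZS, latentCodes(m2)$ZS)
  # trained beats untrained on the held-out edges
  m0 <- trainDigae(sim$dataset, sp, epochs = 0, seed = 4)
  expect_identical(length(lossTrace(m0)), 0L)
  expect_gt(evaluateSplit(m1, sp)$auroc, evaluateSplit(m0, sp)$auroc)
  expect_gt(evaluateSplit(m1, sp)$auroc, 0.8)
})

test_that("untrained models score near chance (random-embedding baseline)", {
  aurocs <- vapply(1:10, function(s) {
    sim <- quickSim(200, 40, seed = s)
    sp <- splitEdges(sim$graph, 0.1, seed = s)
    evaluateSplit(trainDigae(sim$dataset, sp, epochs = 0, seed = s),
                  sp)$auroc
  }, numeric(1))
  expect_gt(mean(aurocs), 0.4)
  expect_lt(mean(aurocs), 0.6)
})

test_that("predicted edge count is non-increasing in the threshold", {
  sim <- quickSim(300, 60, seed = 1)
  sp <- splitEdges(sim$graph, 0.1, seed = 1)
  m <- trainDigae(sim$dataset, sp, epochs = 60, seed = 4)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    nrow(predictedEdges(predictInteractions(m, th))), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(predictInteractions(m, 1.2), "threshold")
  # lazy (blockwise) prediction agrees with the dense path
  rd <- predictInteractions(m, 0.9)
  rl <- predictInteractions(m, 0.9, materialize = FALSE)
  o1 <- order(predictedEdges(rd)[, 1], predictedEdges(rd)[, 2])
  o2 <- order(predictedEdges(rl)[, 1], predictedEdges(rl)[, 2])
  expect_identical(predictedEdges(rd)[o1, ], predictedEdges(rl)[o2, ])
})

test_that("model checkpoints round-trip through disk", {
  sim <- quickSim(300, 60, seed = 1)
  sp <- splitEdges(sim$graph, 0.1, seed = 1)
  m <- trainDigae(sim$dataset, sp, epochs = 10, seed = 4)
  p <- withr::local_tempfile(fileext = ".rds")
  saveDigaeModel(m, p)
  m2 <- loadDigaeModel(p)
  expect_identical(latentCodes(m), latentCodes(m2))
  expect_identical(modelWeights(m), modelWeights(m2))
})

test_that("heterogeneous training uses per-type weights and stays stable", {
  sim <- quickSim(300, 60, seed = 1)
  sp <- splitEdges(sim$graph, 0.1, seed = 1)
  m <- trainDigae(sim$dataset, sp, mode = "heterogeneous", epochs = 60,
                  seed = 4)
  expect_identical(sort(names(modelWeights(m)$WS0)),
                   sort(unique(cellTypes(sim$dataset))))
  expect_gt(evaluateSplit(m, sp)$auroc, 0.8)
})
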