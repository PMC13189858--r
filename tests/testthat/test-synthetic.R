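test_that("config validation rejects inconsistent settings", {
  expect_error(syntheticConfig(nCells = 5, nTypes = 10), "more cell types")
  expect_error(syntheticConfig(nGenes = 50, nTypes = 3,
                               signalGenesPerType = 20), "exceeds nGenes")
  expect_error(syntheticConfig(ligandBlock = 1:5, receptorBlock = 3:8,
                               signalGenesPerType = 0,
                               noiseGeneBlock = integer(0),
                               signatureGeneBlock = integer(0)),
               "overlap")
  expect_error(syntheticConfig(dropoutRate = 1), "dropoutRate")
})

test_that("layout generation is deterministic and respects degenerate sizes", {
  cfg1 <- syntheticConfig(nCells = 1, nGenes = 5, nTypes = 1,
                          signalGenesPerType = 0, ligandBlock = integer(0),
                          receptorBlock = integer(0),
                          noiseGeneBlock = integer(0),
                          signatureGeneBlock = integer(0), seed = 3)
  lay1 <- generateLayout(cfg1)
  expect_identical(nrow(lay1), 1L)
  expect_identical(lay1$cell_type, "type_1")

  cfg <- syntheticConfig(nCells = 200, nGenes = 50, seed = 11)
  expect_identical(generateLayout(cfg), generateLayout(cfg))
})

test_that("full spatial clustering yields spatially coherent types", {
  cfg <- syntheticConfig(nCells = 400, nGenes = 50, nTypes = 2,
                         typeSpatialClustering = 1, seed = 4)
  lay <- generateLayout(cfg)
  # types split by the x median into half planes
  medx <- stats::median(lay$x)
  left <- lay$cell_type[lay$x < medx]
  expect_gte(mean(left == names(which.max(table(left)))), 0.99)
  # away from the boundary, each cell's type matches the majority of its
  # three nearest neighbours (brute-force vote)
  co <- as.matrix(lay[, c("x", "y")])
  D <- as.matrix(dist(co))
  diag(D) <- Inf
  bw <- diff(range(lay$x)) / 10
  ok <- 0; tot <- 0
  for (i in seq_len(nrow(lay))) {
    if (abs(lay$x[i] - medx) < bw) next
    nn <- order(D[i, ])[1:3]
    vote <- names(which.max(table(lay$cell_type[nn])))
    tot <- tot + 1
    ok <- ok + (vote == lay$cell_type[i])
  }
  expect_gte(ok / tot, 0.95)
})

test_that("type programs alone give identical rows within a type", {
  cfg <- syntheticConfig(nCells = 60, nGenes = 30, nTypes = 3,
                         neighborCoupling = 0, noiseSd = 0, dropoutRate = 0,
                         signalGenesPerType = 5,
                         ligandBlock = integer(0),
                         receptorBlock = integer(0),
                         noiseGeneBlock = integer(0),
                         signatureGeneBlock = integer(0), seed = 5)
  sim <- generateDataset(cfg)
  X <- exprMatrix(sim$dataset)
  for (tp in unique(cellTypes(sim$dataset))) {
    rows <- X[cellTypes(sim$dataset) == tp, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
})

test_that("dropout rate matches its Bernoulli target", {
  cfg <- syntheticConfig(nCells = 500, nGenes = 100, dropoutRate = 0.3,
                         noiseSd = 0, seed = 6)
  sim <- generateDataset(cfg)
  frac <- mean(exprMatrix(sim$dataset) == 0)
  expect_gt(frac, 0.28)   # binomial CI at 50 000 trials
  expect_lt(frac, 0.32)
})

test_that("neighbour coupling makes adjacent cells more correlated", {
  # type programs are an independent source of pairwise correlation, so the
  # coupling-monotonicity property is checked on a type-free configuration
  gapFor <- function(coupling, ...) {
    cfg <- syntheticConfig(nCells = 300, nGenes = 60,
                           neighborCoupling = coupling, dropoutRate = 0,
                           seed = 7, ...)
    sim <- generateDataset(cfg)
    X <- exprMatrix(sim$dataset)
    contacts <- undirectedContacts(sim$graph)
    adjCor <- mean(vapply(seq_len(nrow(contacts)), function(e)
      cor(X[contacts[e, 1], ], X[contacts[e, 2], ]), numeric(1)))
    set.seed(1)
    far <- sampleNegativeEdges(sim$graph, nrow(contacts))
    farCor <- mean(vapply(seq_len(nrow(far)), function(e)
      cor(X[far[e, 1], ], X[far[e, 2], ]), numeric(1)))
    adjCor - farCor
  }
  expect_gt(gapFor(2), 0)
  # signal monotonicity across three coupling levels, same seed
  gaps <- vapply(c(0.5, 1, 2), gapFor, numeric(1),
                 signalGenesPerType = 0, typeSpatialClustering = 0)
  expect_true(all(diff(gaps) > -0.02))
})

test_that("generated datasets are reproducible and truth matches the graph", {
  cfg <- syntheticConfig(nCells = 150, nGenes = 50, seed = 9)
  sim1 <- generateDataset(cfg)
  sim2 <- generateDataset(cfg)
  expect_identical(exprMatrix(sim1$dataset), exprMatrix(sim2$dataset))
  expect_identical(spatialCoords(sim1$dataset), spatialCoords(sim2$dataset))
  expect_identical(sim1$truth, sim2$truth)
  # planted directional edges are a subset of graph edges
  gk <- function(p, n) (as.double(p[, 1]) - 1) * n + p[, 2]
  n <- nCells(sim1$dataset)
  expect_true(all(gk(sim1$truth$directedEdges, n) %in%
                    gk(edgeMatrix(sim1$graph), n)))
  # senders are exactly the sender-type cells
  expect_identical(sim1$truth$senderCells,
                   which(cellTypes(sim1$dataset) == "type_1"))
})

test_that("a larger simulation completes and writes round-trippable files", {
  sim <- generateDataset(syntheticConfig(nCells = 2000, nGenes = 200,
                                         seed = 10))
  expect_identical(nCells(sim$dataset), 2000L)
  dir <- withr::local_tempdir()
  writeSyntheticDataset(quickSim(60, 40, seed = 2), dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  ds <- loadDataset(file.path(dir, "expression.csv"),
                    file.path(dir, "coords.csv"),
                    file.path(dir, "types.csv"))
  expect_equal(exprMatrix(ds), exprMatrix(quickSim(60, 40, seed = 2)$dataset),
               tolerance = 1e-6)
})
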