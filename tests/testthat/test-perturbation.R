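test_that("expression noise is multiplicative log2-normal", {
  set.seed(31)
  X <- matrix(rexp(200), 20, 10)
  expect_identical(addNoise(X, 0, seed = 1), X)
  Xn <- addNoise(X, 0.5, seed = 1)
  expect_true(all(Xn >= 0))
  expect_identical(addNoise(X, 0.5, seed = 1), Xn)  # deterministic
  # zero pattern preserved exactly
  X0 <- X; X0[sample(200, 50)] <- 0
  expect_identical(addNoise(X0, 1, seed = 2) == 0, X0 == 0)
  # realised sd of log2 fold changes matches sigma
  Xl <- matrix(rexp(1e5), 1000, 100)
  r <- log2(addNoise(Xl, 1, seed = 3) / Xl)
  expect_equal(sd(r), 1, tolerance = 0.01)
  expect_error(addNoise(X, -1), "sigma")
})

test_that("edge removal operates on undirected contacts with matched negatives", {
  set.seed(32)
  co <- cbind(runif(80), runif(80))
  g <- buildAdjacency(co, computeDistanceThreshold(co), k = 3)
  nc <- nrow(undirectedContacts(g))
  r0 <- removeEdges(g, 0, seed = 1)
  expect_identical(edgeMatrix(r0$graph), edgeMatrix(g))
  expect_identical(nrow(r0$removed), 0L)
  r <- removeEdges(g, 0.5, seed = 1)
  expect_identical(nrow(r$removed), as.integer(round(0.5 * nc)))
  expect_identical(nrow(undirectedContacts(r$graph)),
                   nc - as.integer(round(0.5 * nc)))
  # removed and remaining partition the original contacts
  allC <- rbind(r$removed, undirectedContacts(r$graph))
  expect_identical(anyDuplicated(allC), 0L)
  expect_identical(nrow(allC), nc)
  # both orientations removed together; negatives matched and disjoint
  e <- edgeMatrix(r$graph)
  keys <- paste(e[, 1], e[, 2])
  expect_true(all(paste(e[, 2], e[, 1]) %in% keys))
  expect_identical(nrow(r$negatives), nrow(r$removedPairs))
  expect_false(any(paste(r$negatives[, 1], r$negatives[, 2]) %in%
                     paste(edgeMatrix(g)[, 1], edgeMatrix(g)[, 2])))
  expect_error(removeEdges(g, 1), "fraction")
})

test_that("gene dropout removes whole columns and keeps the rest bitwise", {
  set.seed(33)
  X <- matrix(rexp(500), 5, 100)
  expect_identical(dropoutGenes(X, 0, seed = 1)$X, X)
  d <- dropoutGenes(X, 0.25, seed = 1)
  expect_identical(ncol(d$X), 75L)
  expect_identical(d$X, X[, d$kept])
  expect_error(dropoutGenes(X[, 1:2], 0.9), "all genes")
})

test_that("value dropout zeroes an exact quota of non-zero entries", {
  set.seed(34)
  X <- matrix(0, 4, 5)
  X[sample(20, 8)] <- rexp(8)
  expect_identical(dropoutValues(X, 0, seed = 1), X)
  Xs <- dropoutValues(X, 0.5, seed = 1)
  expect_identical(sum(Xs != 0), 4L)
  expect_true(all(Xs[X == 0] == 0))
  # random 20x10 matrix: zeros untouched, quota exact
  Y <- matrix(rexp(200), 20, 10); Y[sample(200, 60)] <- 0
  Ys <- dropoutValues(Y, 0.3, seed = 2)
  expect_identical(sum(Ys != 0), 140L - as.integer(round(0.3 * 140)))
  expect_true(all(Ys[Y == 0] == 0))
  # composing never leaves more nonzeros than either single application
  Ya <- dropoutValues(Y, 0.4, seed = 3)
  Yab <- dropoutValues(Ya, 0.2, seed = 4)
  expect_lte(sum(Yab != 0), sum(Ya != 0))
  expect_lte(sum(Yab != 0), sum(dropoutValues(Y, 0.2, seed = 4) != 0))
})

test_that("ligand/receptor initialisation builds the stated submatrices", {
  X <- matrix(rexp(40), 10, 4,
              dimnames = list(paste0("c", 1:10), c("La", "Rb", "Lc", "Both")))
  ds <- SpatialDataset(X, cbind(1:10, 1:10))
  tab <- data.frame(ligand = c("La", "Lc", "Both"),
                    receptor = c("Rb", "Both", "Rb"),
                    category = c("Cell-Cell Contact", "Secreted Signaling",
                                 "Cell-Cell Contact"))
  init <- lrInitialize(ds, tab)
  # dedup per side; a gene on both sides appears once in each matrix
  expect_identical(init$ligands, c("La", "Lc", "Both"))
  expect_identical(init$receptors, c("Rb", "Both"))
  expect_identical(init$S0, X[, c("La", "Lc", "Both")])
  expect_identical(init$T0, X[, c("Rb", "Both")])
  # category filter restricts the panel
  initC <- lrInitialize(ds, tab, categoryFilter = "Cell-Cell Contact")
  expect_identical(initC$ligands, c("La", "Both"))
  expect_identical(initC$receptors, "Rb")
  # single pair, both genes present
  init1 <- lrInitialize(ds, tab[1, ])
  expect_identical(ncol(init1$S0), 1L)
  expect_identical(as.numeric(init1$S0), as.numeric(X[, "La"]))
  # all genes missing is an explicit empty-panel error
  tabM <- data.frame(ligand = "Nope", receptor = "Rb",
                     category = "Cell-Cell Contact")
  expect_error(lrInitialize(ds, tabM), "empty-panel.*Nope")
  # case folding flag
  tabF <- data.frame(ligand = "LA", receptor = "RB",
                     category = "Cell-Cell Contact")
  expect_error(lrInitialize(ds, tabF), "empty-panel")
  expect_identical(lrInitialize(ds, tabF, caseFold = TRUE)$ligands, "La")
})

test_that("ligand/receptor tables are validated on read", {
  d <- withr::local_tempdir()
  p <- file.path(d, "lr.csv")
  write.csv(data.frame(ligand = c("A", "A", "B"),
                       receptor = c("R1", "R1", "R2"),
                       category = c("Cell-Cell Contact", "Cell-Cell Contact",
                                    "Extra Cellular Matrix")),
            p, row.names = FALSE)
  tab <- readLRTable(p)
  expect_identical(nrow(tab), 2L)  # duplicate pair dropped
  expect_identical(tab$category[2], "ECM")
  write.csv(data.frame(ligand = "A", receptor = "R", category = "Weird"),
            p, row.names = FALSE)
  expect_error(readLRTable(p), "unknown ligand-receptor categories")
})

test_that("perturbations leave their inputs untouched (purity)", {
  set.seed(35)
  X <- matrix(rexp(100), 10, 10)
  Xcopy <- X + 0
  invisible(addNoise(X, 1, seed = 1))
  invisible(dropoutValues(X, 0.3, seed = 1))
  invisible(dropoutGenes(X, 0.3, seed = 1))
  expect_identical(X, Xcopy)
  co <- cbind(runif(40), runif(40))
  g <- buildAdjacency(co, computeDistanceThreshold(co), 3)
  e <- edgeMatrix(g) + 0L
  invisible(removeEdges(g, 0.3, seed = 1))
  expect_identical(edgeMatrix(g), e)
})
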