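# Brute-force reference implementations used as independent oracles, plus
# small fixture builders. All oracles are deliberately naive O(N^2) code
# with no shared logic with the package internals.

# All-pairs contact graph: for each cell, its k nearest neighbours within
# the threshold, union over cells, symmetrised.
bruteContactGraph <- function(coords, threshold, k) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    sel <- ord[seq_len(min(k, n - 1))]
    sel <- sel[d[sel] <= threshold]
    for (j in sel) pairs <- rbind(pairs, c(min(i, j), max(i, j)))
  }
  unique(pairs)
}

# Per-node message-passing loop: row i of the output sums Ahat[i, j] *
# (in_j %*% W_j) over j, where W_j is the weight matrix assigned to node j.
bruteAggregate <- function(Ahat, input, Wper) {
  A <- as.matrix(Ahat)
  n <- nrow(A)
  out <- matrix(0, n, ncol(Wper[[1]]))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (A[i, j] != 0)
        out[i, ] <- out[i, ] + A[i, j] *
          as.numeric(input[j, , drop = FALSE] %*% Wper[[j]])
    }
  }
  out
}

# Exhaustive concordant-pair AUROC (ties count one half).
bruteAUROC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Normalised adjacency from first principles (dense).
bruteAhat <- function(A, alpha, beta, selfLoops = TRUE) {
  A <- as.matrix(A)
  if (selfLoops) A <- A + diag(nrow(A))
  dout <- rowSums(A); din <- colSums(A)
  dout[dout == 0] <- 1; din[din == 0] <- 1
  diag(dout^(-beta)) %*% A %*% diag(din^(-alpha))
}

# Random small directed graph fixture (symmetric pairs, no self loops).
randomSmallGraph <- function(n, pEdge = 0.4) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < pEdge
  contacts <- pairs[keep, , drop = FALSE]
  edges <- rbind(contacts, contacts[, 2:1, drop = FALSE])
  CellGraph(n, edges)
}

# Moderate synthetic fixture shared by downstream tests (cached per session).
quickSim <- local({
  cache <- new.env()
  function(nCells = 300, nGenes = 60, seed = 1, ...) {
    key <- paste(nCells, nGenes, seed, ...)
    if (is.null(cache[[key]]))
      cache[[key]] <- generateDataset(
        syntheticConfig(nCells = nCells, nGenes = nGenes, seed = seed, ...))
    cache[[key]]
  }
})
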