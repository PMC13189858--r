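# Directed graph autoencoder: degree-weighted directed convolutions, two-layer
# encoder producing separate sender (Z_S) and receiver (Z_T) codes, asymmetric
# inner-product decoder, and full-batch Adam training with hand-derived
# gradients.

#' Degree-normalised adjacency for directed message passing
#'
#' Computes \eqn{\hat A = (\tilde D^+)^{-\beta} \tilde A (\tilde D^-)^{-\alpha}}
#' where \eqn{\tilde A} is the adjacency with self loops added (when
#' requested), and \eqn{\tilde D^+}, \eqn{\tilde D^-} the out-/in-degree
#' diagonals of \eqn{\tilde A}. A residual zero degree is treated as scaling
#' factor 1, so isolated cells never produce infinities.
#'
#' @param graph a \linkS4class{CellGraph}.
#' @param alpha,beta in-degree / out-degree exponents (alpha = beta = 0
#'   leaves the adjacency unchanged).
#' @param addSelfLoops add the identity before computing degrees (default
#'   TRUE, the usual GCN convention).
#' @return A \linkS4class{NormalizedAdjacency}.
#' @examples
#' g <- CellGraph(2, rbind(c(1L, 2L)))
#' round(as.matrix(ahatMatrix(normalizeAdjacency(g, 0.5, 0.5))), 4)
#' @export
normalizeAdjacency <- function(graph, alpha = 0.5, beta = 0.5,
                               addSelfLoops = TRUE) {
  A <- adjacencyMatrix(graph, selfLoops = FALSE)
  if (length(A@x) && any(A@x < 0))
    stop("validation error: adjacency has negative entries")
  At <- if (addSelfLoops) A + Matrix::Diagonal(nNodes(graph)) else A
  dOut <- Matrix::rowSums(At)
  dIn <- Matrix::colSums(At)
  dOut[dOut == 0] <- 1
  dIn[dIn == 0] <- 1
  Ahat <- Matrix::Diagonal(x = dOut^(-beta)) %*% At %*%
    Matrix::Diagonal(x = dIn^(-alpha))
  new("NormalizedAdjacency", Ahat = methods::as(Ahat, "generalMatrix"),
      alpha = alpha, beta = beta, selfLoopsAdded = addSelfLoops)
}

.ahat <- function(x) {
  if (methods::is(x, "NormalizedAdjacency")) x@Ahat else x
}

#' One directed graph convolution layer (homogeneous)
#'
#' Simultaneous update of the sender and receiver channels: the sender
#' embedding of a cell aggregates the receiver embeddings of the cells it
#' points to, and vice versa. Both outputs are computed from the *input* S
#' and T (no in-place sequencing):
#' \deqn{S' = f(\hat A\, T\, W_T), \qquad T' = f(\hat A^\top S\, W_S).}
#'
#' @param Ahat a \linkS4class{NormalizedAdjacency} (or plain matrix).
#' @param S,T current sender / receiver embeddings (N x d).
#' @param WS,WT learnable weights for the sender / receiver channel.
#' @param activation elementwise activation, default identity.
#' @return list with matrices `S` and `T`.
#' @export
directedLayer <- function(Ahat, S, T, WS, WT, activation = identity) {
  Ah <- .ahat(Ahat)
  if (ncol(S) != nrow(WS) || ncol(T) != nrow(WT))
    stop("dimension error: weight shapes do not match embeddings")
  list(S = activation(as.matrix(Ah %*% (T %*% WT))),
       T = activation(as.matrix(Matrix::t(Ah) %*% (S %*% WS))))
}

# Row-wise type-specific transform: row j of the result is M[j, ] %*%
# Wlist[[type(j)]]. All per-type matrices must share output width.
.rowTypeTransform <- function(M, Wlist, typeIdx) {
  out <- matrix(0, nrow(M), ncol(Wlist[[1]]))
  for (k in seq_along(Wlist)) {
    rows <- which(typeIdx == k)
    if (length(rows))
      out[rows, ] <- M[rows, , drop = FALSE] %*% Wlist[[k]]
  }
  out
}

#' One directed graph convolution layer (heterogeneous)
#'
#' As \code{\link{directedLayer}}, but each node's embedding row is first
#' transformed by its own cell type's weight matrix before aggregation, so
#' different cell types occupy different semantic spaces.
#'
#' @param Ahat a \linkS4class{NormalizedAdjacency} (or plain matrix).
#' @param S,T current embeddings.
#' @param cellTypes character/factor of per-node types.
#' @param WSlist,WTlist named lists of per-type weight matrices; every
#'   observed type must have weights registered.
#' @param activation elementwise activation, default identity.
#' @return list with matrices `S` and `T`.
#' @export
heteroDirectedLayer <- function(Ahat, S, T, cellTypes, WSlist, WTlist,
                                activation = identity) {
  Ah <- .ahat(Ahat)
  lev <- names(WSlist)
  miss <- setdiff(unique(as.character(cellTypes)), lev)
  if (length(miss))
    stop("missing-type error: no weights for type(s) ",
         paste(miss, collapse = ", "))
  typeIdx <- match(as.character(cellTypes), lev)
  list(S = activation(as.matrix(Ah %*% .rowTypeTransform(T, WTlist, typeIdx))),
       T = activation(as.matrix(Matrix::t(Ah) %*%
                                  .rowTypeTransform(S, WSlist, typeIdx))))
}

#' Two-layer directed encoder
#'
#' Homogeneous mode computes
#' \deqn{Z_S = \hat A\,\mathrm{ReLU}(\hat A^\top S^{(0)} W_S^{(0)})\,W_T^{(1)},
#'  \quad Z_T = \hat A^\top\,\mathrm{ReLU}(\hat A\, T^{(0)} W_T^{(0)})\,
#'  W_S^{(1)},}
#' i.e. a ReLU directed layer followed by a linear one. Heterogeneous mode
#' substitutes the type-specific transform at each stage. By default both
#' channels start from the expression matrix (\eqn{S^{(0)} = T^{(0)} = X});
#' ligand/receptor restricted initialisation passes different S0 and T0.
#'
#' @param Ahat a \linkS4class{NormalizedAdjacency}.
#' @param S0,T0 input features (N x M_S, N x M_T).
#' @param weights list with WS0, WT0, WS1, WT1 (per-type lists of these in
#'   heterogeneous mode).
#' @param mode "homogeneous" or "heterogeneous".
#' @param cellTypes per-node types (heterogeneous mode only).
#' @return list with latent matrices `ZS` and `ZT`.
#' @export
digaeEncode <- function(Ahat, S0, T0 = S0, weights,
                        mode = c("homogeneous", "heterogeneous"),
                        cellTypes = NULL) {
  mode <- match.arg(mode)
  Ah <- .ahat(Ahat)
  Aht <- Matrix::t(Ah)
  if (mode == "homogeneous") {
    if (ncol(S0) != nrow(weights$WS0) || ncol(T0) != nrow(weights$WT0))
      stop("dimension error: input width does not match first-layer weights")
    ZS <- as.matrix(Ah %*% (relu(as.matrix(Aht %*% (S0 %*% weights$WS0))) %*%
                              weights$WT1))
    ZT <- as.matrix(Aht %*% (relu(as.matrix(Ah %*% (T0 %*% weights$WT0))) %*%
                               weights$WS1))
  } else {
    if (is.null(cellTypes)) stop("heterogeneous mode requires cellTypes")
    lev <- names(weights$WS0)
    typeIdx <- match(as.character(cellTypes), lev)
    if (anyNA(typeIdx))
      stop("missing-type error: cell types without registered weights")
    H <- relu(as.matrix(Aht %*% .rowTypeTransform(S0, weights$WS0, typeIdx)))
    ZS <- as.matrix(Ah %*% .rowTypeTransform(H, weights$WT1, typeIdx))
    G <- relu(as.matrix(Ah %*% .rowTypeTransform(T0, weights$WT0, typeIdx)))
    ZT <- as.matrix(Aht %*% .rowTypeTransform(G, weights$WS1, typeIdx))
  }
  list(ZS = ZS, ZT = ZT)
}

#' Asymmetric inner-product decoder
#'
#' \eqn{A'_{ij} = \sigma(\langle Z_{S,i}, Z_{T,j}\rangle)}: the probability
#' of a *directed* edge i -> j. No symmetrisation is applied, so
#' \eqn{A' \ne A'^\top} whenever \eqn{Z_S \ne Z_T}.
#'
#' @param ZS,ZT latent sender / receiver codes (N x d).
#' @param threshold edge-calling threshold in (0,1); pairs with probability
#'   >= threshold (self pairs excluded) become predicted edges.
#' @return A \linkS4class{ReconstructionResult}.
#' @export
digaeDecode <- function(ZS, ZT, threshold = 0.5) {
  if (ncol(ZS) != ncol(ZT))
    stop("dimension error: latent dims of ZS and ZT differ")
  if (threshold <= 0 || threshold >= 1)
    stop("config error: threshold must be in (0,1)")
  probs <- sigmoid(ZS %*% t(ZT))
  eps <- 1e-12
  probs[probs < eps] <- eps
  probs[probs > 1 - eps] <- 1 - eps
  hit <- probs >= threshold
  diag(hit) <- FALSE
  edges <- which(hit, arr.ind = TRUE)
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("source", "target")))
  new("ReconstructionResult", probs = probs, threshold = threshold,
      edges = edges, metrics = list())
}

#' Binary cross-entropy reconstruction loss
#'
#' Mean BCE over positive edges (label 1) and sampled negative pairs (label
#' 0), with probabilities clipped to [1e-7, 1 - 1e-7] for numerical safety.
#'
#' @param Aprime N x N probability matrix (or \linkS4class{ReconstructionResult}).
#' @param trainPos,trainNeg 2-column index matrices of ordered pairs.
#' @return non-negative scalar loss.
#' @export
reconstructionLoss <- function(Aprime, trainPos, trainNeg) {
  if (methods::is(Aprime, "ReconstructionResult"))
    Aprime <- edgeProbabilities(Aprime)
  if (nrow(trainPos) == 0L) stop("training error: empty positive edge set")
  p <- c(Aprime[trainPos], Aprime[trainNeg])
  y <- c(rep(1, nrow(trainPos)), rep(0, nrow(trainNeg)))
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Glorot-uniform weight matrix.
.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.initWeights <- function(mS, mT, hidden, latent, mode, typeLevels) {
  one <- function() list(WS0 = .glorot(mS, hidden), WT0 = .glorot(mT, hidden),
                         WS1 = .glorot(hidden, latent),
                         WT1 = .glorot(hidden, latent))
  if (mode == "homogeneous") return(one())
  perType <- lapply(typeLevels, function(k) one())
  names(perType) <- typeLevels
  # reshape: weights$WS0 is a named list over types, etc.
  out <- lapply(c("WS0", "WT0", "WS1", "WT1"), function(nm)
    lapply(perType, `[[`, nm))
  names(out) <- c("WS0", "WT0", "WS1", "WT1")
  out
}

# Adam state and update for a flat list of matrices.
.adamInit <- function(ws) lapply(ws, function(w) {
  if (is.list(w)) lapply(w, function(wk) list(m = wk * 0, v = wk * 0))
  else list(m = w * 0, v = w * 0)
})

.adamStep <- function(w, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(w = w - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Train the directed graph autoencoder
#'
#' Builds the message-passing operator from the *training* edges only (held
#' out test edges never leak into \eqn{\hat A}), then minimises the binary
#' cross-entropy of the decoded probabilities over training edges and
#' freshly resampled non-adjacent negative pairs (one negative per positive,
#' resampled every epoch) with full-batch Adam. Deterministic given `seed`.
#'
#' @param dataset a \linkS4class{SpatialDataset}.
#' @param split an \linkS4class{EdgeSplit} built on the dataset's graph.
#' @param mode "homogeneous" or "heterogeneous" (the latter requires cell
#'   types on the dataset).
#' @param hidden,latent layer widths (input M -> hidden -> latent).
#' @param alpha,beta degree-normalisation exponents.
#' @param epochs number of full-batch Adam epochs (0 returns the initialised
#'   model with its random-weight codes).
#' @param lr Adam learning rate.
#' @param seed integer seed controlling initialisation and negative
#'   sampling.
#' @param S0,T0 optional input features overriding the default
#'   \eqn{S^{(0)} = T^{(0)} = X} (ligand/receptor restricted initialisation;
#'   widths may differ, first-layer weights are sized accordingly).
#' @param addSelfLoops self-loop augmentation before normalisation.
#' @param scaleInputs standardise input feature columns (z-score, then
#'   shifted ReLU-friendly) before training; default TRUE.
#' @param verbose print loss every 50 epochs.
#' @return A trained \linkS4class{DigaeModel} with cached `ZS`, `ZT`,
#'   the normalised adjacency used, and the per-epoch loss trace.
#' @export
trainDigae <- function(dataset, split,
                       mode = c("homogeneous", "heterogeneous"),
                       hidden = 64, latent = 32, alpha = 0.5, beta = 0.5,
                       epochs = 200, lr = 0.01, seed = 0,
                       S0 = NULL, T0 = NULL, addSelfLoops = TRUE,
                       scaleInputs = TRUE, verbose = FALSE) {
  mode <- match.arg(mode)
  N <- nCells(dataset)
  X <- exprMatrix(dataset)
  if (is.null(S0)) S0 <- X
  if (is.null(T0)) T0 <- if (is.null(S0)) X else S0
  if (scaleInputs) {
    S0 <- .scaleFeatures(S0)
    T0 <- .scaleFeatures(T0)
  }
  types <- cellTypes(dataset)
  if (mode == "heterogeneous" && is.null(types))
    stop("heterogeneous mode requires cell types on the dataset")
  typeLevels <- if (mode == "heterogeneous") levels(factor(types))
                else character(0)
  typeIdx <- if (mode == "heterogeneous") match(types, typeLevels) else NULL

  trainPos <- splitPairs(split, "trainPos")
  if (nrow(trainPos) == 0L) stop("training error: empty positive edge set")
  trainGraph <- CellGraph(N, trainPos)
  Ahat <- normalizeAdjacency(trainGraph, alpha = alpha, beta = beta,
                             addSelfLoops = addSelfLoops)
  Ah <- Ahat@Ahat
  Aht <- Matrix::t(Ah)

  withSeed(seed, {
    ws <- .initWeights(ncol(S0), ncol(T0), hidden, latent, mode, typeLevels)
    adam <- .adamInit(ws)
    nPos <- nrow(trainPos)
    trace <- numeric(0)
    forward <- function() {
      if (mode == "homogeneous") {
        P <- as.matrix(Aht %*% (S0 %*% ws$WS0)); H <- relu(P)
        ZS <- as.matrix(Ah %*% (H %*% ws$WT1))
        Q <- as.matrix(Ah %*% (T0 %*% ws$WT0)); G <- relu(Q)
        ZT <- as.matrix(Aht %*% (G %*% ws$WS1))
        list(P = P, H = H, ZS = ZS, Q = Q, G = G, ZT = ZT)
      } else {
        P <- as.matrix(Aht %*% .rowTypeTransform(S0, ws$WS0, typeIdx))
        H <- relu(P)
        ZS <- as.matrix(Ah %*% .rowTypeTransform(H, ws$WT1, typeIdx))
        Q <- as.matrix(Ah %*% .rowTypeTransform(T0, ws$WT0, typeIdx))
        G <- relu(Q)
        ZT <- as.matrix(Aht %*% .rowTypeTransform(G, ws$WS1, typeIdx))
        list(P = P, H = H, ZS = ZS, Q = Q, G = G, ZT = ZT)
      }
    }
    fw <- forward()
    if (epochs > 0) for (ep in seq_len(epochs)) {
      neg <- sampleNegativeEdges(trainGraph, nPos)
      pairs <- rbind(trainPos, neg)
      y <- c(rep(1, nPos), rep(0, nPos))
      s <- rowSums(fw$ZS[pairs[, 1], , drop = FALSE] *
                     fw$ZT[pairs[, 2], , drop = FALSE])
      p <- sigmoid(s)
      pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
      if (!is.finite(loss))
        stop("divergence error: non-finite loss at epoch ", ep)
      trace <- c(trace, loss)
      if (verbose && ep %% 50 == 0)
        message(sprintf("epoch %d: loss %.4f", ep, loss))
      g <- (p - y) / length(y)
      Gm <- Matrix::sparseMatrix(i = pairs[, 1], j = pairs[, 2], x = g,
                                 dims = c(N, N))
      dZS <- as.matrix(Gm %*% fw$ZT)
      dZT <- as.matrix(Matrix::t(Gm) %*% fw$ZS)
      if (mode == "homogeneous") {
        AhtdZS <- as.matrix(Aht %*% dZS)
        gWT1 <- crossprod(fw$H, AhtdZS)
        dP <- (AhtdZS %*% t(ws$WT1)) * (fw$P > 0)
        gWS0 <- crossprod(S0, as.matrix(Ah %*% dP))
        AhdZT <- as.matrix(Ah %*% dZT)
        gWS1 <- crossprod(fw$G, AhdZT)
        dQ <- (AhdZT %*% t(ws$WS1)) * (fw$Q > 0)
        gWT0 <- crossprod(T0, as.matrix(Aht %*% dQ))
        for (nm in c("WS0", "WT0", "WS1", "WT1")) {
          gmat <- switch(nm, WS0 = gWS0, WT0 = gWT0, WS1 = gWS1, WT1 = gWT1)
          up <- .adamStep(ws[[nm]], gmat, adam[[nm]], lr, ep)
          ws[[nm]] <- up$w; adam[[nm]] <- up$st
        }
      } else {
        dM1 <- as.matrix(Aht %*% dZS)          # ZS = Ah %*% M1
        dH <- matrix(0, N, hidden)
        for (k in seq_along(typeLevels)) {
          rows <- which(typeIdx == k)
          if (!length(rows)) next
          gWT1k <- crossprod(fw$H[rows, , drop = FALSE],
                             dM1[rows, , drop = FALSE])
          dH[rows, ] <- dM1[rows, , drop = FALSE] %*% t(ws$WT1[[k]])
          up <- .adamStep(ws$WT1[[k]], gWT1k, adam$WT1[[k]], lr, ep)
          ws$WT1[[k]] <- up$w; adam$WT1[[k]] <- up$st
        }
        dP <- dH * (fw$P > 0)
        dM0 <- as.matrix(Ah %*% dP)            # P = Aht %*% M0
        dM3 <- as.matrix(Ah %*% dZT)           # ZT = Aht %*% M3
        dG <- matrix(0, N, hidden)
        for (k in seq_along(typeLevels)) {
          rows <- which(typeIdx == k)
          if (!length(rows)) next
          gWS0k <- crossprod(S0[rows, , drop = FALSE],
                             dM0[rows, , drop = FALSE])
          up <- .adamStep(ws$WS0[[k]], gWS0k, adam$WS0[[k]], lr, ep)
          ws$WS0[[k]] <- up$w; adam$WS0[[k]] <- up$st
          gWS1k <- crossprod(fw$G[rows, , drop = FALSE],
                             dM3[rows, , drop = FALSE])
          dG[rows, ] <- dM3[rows, , drop = FALSE] %*% t(ws$WS1[[k]])
          up <- .adamStep(ws$WS1[[k]], gWS1k, adam$WS1[[k]], lr, ep)
          ws$WS1[[k]] <- up$w; adam$WS1[[k]] <- up$st
        }
        dQ <- dG * (fw$Q > 0)
        dM2 <- as.matrix(Aht %*% dQ)           # Q = Ah %*% M2
        for (k in seq_along(typeLevels)) {
          rows <- which(typeIdx == k)
          if (!length(rows)) next
          gWT0k <- crossprod(T0[rows, , drop = FALSE],
                             dM2[rows, , drop = FALSE])
          up <- .adamStep(ws$WT0[[k]], gWT0k, adam$WT0[[k]], lr, ep)
          ws$WT0[[k]] <- up$w; adam$WT0[[k]] <- up$st
        }
      }
      fw <- forward()
    }
    new("DigaeModel", mode = mode, weights = ws, typeLevels = typeLevels,
        ZS = fw$ZS, ZT = fw$ZT, Ahat = Ahat,
        hyper = list(inputDims = c(ncol(S0), ncol(T0)), hidden = hidden,
                     latent = latent, alpha = alpha, beta = beta, lr = lr,
                     epochs = epochs, seed = as.integer(seed),
                     scaleInputs = scaleInputs,
                     addSelfLoops = addSelfLoops),
        lossTrace = trace)
  })
}

# Feature scaling used on encoder inputs: centre each column, then divide
# the whole matrix by one global scale (the root-mean-square column sd).
# A single scalar, not per-column standardisation: relative variances
# between genes are information (low-variance background genes should not
# be inflated to the same footing as structured ones).
.scaleFeatures <- function(M) {
  mu <- colMeans(M)
  Mc <- sweep(M, 2, mu, "-")
  s <- sqrt(mean(Mc^2))
  if (!is.finite(s) || s == 0) s <- 1
  Mc / s
}

#' Re-encode new inputs with a frozen trained model
#'
#' Runs the encoder with the model's trained weights and its stored
#' message-passing operator on (possibly perturbed) input features — the
#' primitive behind permutation sensitivity scoring.
#'
#' @param model a trained \linkS4class{DigaeModel}.
#' @param S0,T0 input feature matrices: pass what the model was trained on,
#'   modified as needed (T0 defaults to S0).
#' @param cellTypes per-cell types (required in heterogeneous mode; defaults
#'   to none).
#' @return list with `ZS`, `ZT`.
#' @export
modelEncode <- function(model, S0, T0 = S0, cellTypes = NULL) {
  if (isTRUE(model@hyper$scaleInputs)) {
    S0 <- .scaleFeatures(S0)
    T0 <- .scaleFeatures(T0)
  }
  digaeEncode(model@Ahat, S0, T0, model@weights, mode = model@mode,
              cellTypes = cellTypes)
}

#' Edge probabilities for specific ordered pairs
#'
#' @param model a trained \linkS4class{DigaeModel} (or a list with ZS, ZT).
#' @param pairs 2-column index matrix of ordered pairs.
#' @return numeric vector of probabilities.
#' @export
scoreEdgePairs <- function(model, pairs) {
  Z <- if (methods::is(model, "DigaeModel")) latentCodes(model) else model
  sigmoid(rowSums(Z$ZS[pairs[, 1], , drop = FALSE] *
                    Z$ZT[pairs[, 2], , drop = FALSE]))
}

#' Reconstruct the full interaction network from a trained model
#'
#' Decodes the cached latent codes into a dense probability matrix and a
#' thresholded directed edge list (self pairs excluded; the comparison is
#' inclusive, probability >= threshold). For very large N pass
#' `materialize = FALSE` to get only the edge list, computed blockwise.
#'
#' @param model a trained \linkS4class{DigaeModel}.
#' @param threshold edge-calling threshold in (0,1).
#' @param materialize keep the dense N x N probability matrix (default TRUE
#'   for N <= 20000).
#' @return A \linkS4class{ReconstructionResult}.
#' @export
predictInteractions <- function(model, threshold = 0.5,
                                materialize = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop("config error: threshold must be in (0,1)")
  Z <- latentCodes(model)
  N <- nrow(Z$ZS)
  if (is.null(materialize)) materialize <- N <= 20000
  if (materialize) return(digaeDecode(Z$ZS, Z$ZT, threshold))
  edges <- vector("list", 0)
  block <- 2048L
  for (start in seq(1L, N, by = block)) {
    rows <- start:min(start + block - 1L, N)
    p <- sigmoid(Z$ZS[rows, , drop = FALSE] %*% t(Z$ZT))
    hit <- which(p >= threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      hit[, 1] <- rows[hit[, 1]]
      hit <- hit[hit[, 1] != hit[, 2], , drop = FALSE]
      edges[[length(edges) + 1L]] <- hit
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else matrix(integer(0), 0, 2)
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("source", "target")))
  new("ReconstructionResult", probs = matrix(numeric(0), 0, 0),
      threshold = threshold, edges = edges, metrics = list())
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single RDS archive holding all weight matrices, the
#' latent codes, the normalised adjacency, hyperparameters and seed.
#'
#' @param model a \linkS4class{DigaeModel}.
#' @param path checkpoint path.
#' @return `saveDigaeModel` returns `path` invisibly; `loadDigaeModel`
#'   returns the model.
#' @export
saveDigaeModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveDigaeModel
#' @export
loadDigaeModel <- function(path) {
  m <- readRDS(path)
  stopifnot(methods::is(m, "DigaeModel"))
  m
}
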