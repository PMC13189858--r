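#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t crossprod readMM writeMM
NULL

#' SpatialDataset: expression plus coordinates for one tissue section
#'
#' Container for a single-cell spatial transcriptomics dataset: a
#' non-negative cells-by-genes expression matrix, 2-D spatial coordinates per
#' cell, and optional cell-type labels. Cell ids and gene names live in the
#' dimnames of the expression matrix and must be unique.
#'
#' @slot exprs numeric matrix, cells x genes, non-negative, finite; rownames
#'   are cell ids, colnames are gene names.
#' @slot coords numeric matrix, cells x 2 (columns x, y), finite.
#' @slot cellTypes character vector of per-cell type labels (length 0 when
#'   absent; no missing values when present).
#' @export
setClass("SpatialDataset",
  representation(exprs = "matrix", coords = "matrix", cellTypes = "character"))

setValidity("SpatialDataset", function(object) {
  msg <- character(0)
  X <- object@exprs
  co <- object@coords
  if (!is.numeric(X)) msg <- c(msg, "exprs must be numeric")
  if (anyNA(X) || any(!is.finite(X))) msg <- c(msg, "exprs contains NA/Inf")
  else if (any(X < 0)) msg <- c(msg, "exprs must be non-negative")
  if (ncol(co) != 2L) msg <- c(msg, "coords must have 2 columns")
  if (nrow(co) != nrow(X)) msg <- c(msg, "coords/exprs row mismatch")
  if (anyNA(co) || any(!is.finite(co))) msg <- c(msg, "coords contain NA/Inf")
  if (is.null(rownames(X)) || anyDuplicated(rownames(X)))
    msg <- c(msg, "cell ids (rownames of exprs) must exist and be unique")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    msg <- c(msg, "gene names (colnames of exprs) must exist and be unique")
  ct <- object@cellTypes
  if (length(ct) > 0L) {
    if (length(ct) != nrow(X)) msg <- c(msg, "cellTypes length mismatch")
    if (anyNA(ct)) msg <- c(msg, "cellTypes contain NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpatialDataset
#'
#' @param exprs cells x genes numeric matrix (non-negative).
#' @param coords cells x 2 numeric matrix of spatial coordinates.
#' @param cellTypes optional character/factor vector of per-cell labels.
#' @param cellIds,geneNames optional ids; default to existing dimnames or
#'   `cell_1..N` / `gene_1..M`.
#' @return A \linkS4class{SpatialDataset}.
#' @examples
#' X <- matrix(rpois(20, 4), 5, 4)
#' ds <- SpatialDataset(X, cbind(runif(5), runif(5)))
#' nCells(ds)
#' @export
SpatialDataset <- function(exprs, coords, cellTypes = NULL,
                           cellIds = NULL, geneNames = NULL) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(cellIds)) {
    cellIds <- rownames(exprs)
    if (is.null(cellIds)) cellIds <- paste0("cell_", seq_len(nrow(exprs)))
  }
  if (is.null(geneNames)) {
    geneNames <- colnames(exprs)
    if (is.null(geneNames)) geneNames <- paste0("gene_", seq_len(ncol(exprs)))
  }
  dimnames(exprs) <- list(as.character(cellIds), as.character(geneNames))
  colnames(coords) <- c("x", "y")
  rownames(coords) <- rownames(exprs)
  new("SpatialDataset", exprs = exprs, coords = coords,
      cellTypes = if (is.null(cellTypes)) character(0)
                  else as.character(cellTypes))
}

#' CellGraph: directed cell adjacency graph
#'
#' Ordered edge pairs over `nNodes` cells (1-based indices). Spatial contact
#' graphs store both orientations of every contact; derived quantities
#' (augmented adjacency, in/out degree matrices) are computed by
#' \code{\link{adjacencyMatrix}} and \code{\link{normalizeAdjacency}}.
#'
#' @slot nNodes integer number of cells.
#' @slot edges 2-column integer matrix of ordered (source, target) pairs.
#' @slot selfLoopsAdded logical; TRUE only for graphs whose edge list already
#'   contains self loops (construction from coordinates never adds them).
#' @export
setClass("CellGraph",
  representation(nNodes = "integer", edges = "matrix",
                 selfLoopsAdded = "logical"))

setValidity("CellGraph", function(object) {
  msg <- character(0)
  e <- object@edges
  n <- object@nNodes
  if (n < 0L) msg <- c(msg, "nNodes must be >= 0")
  if (ncol(e) != 2L) msg <- c(msg, "edges must have 2 columns")
  if (nrow(e) > 0L) {
    if (!is.integer(e)) msg <- c(msg, "edges must be integer")
    if (min(e) < 1L || max(e) > n) msg <- c(msg, "edge indices out of range")
    if (anyDuplicated(e)) msg <- c(msg, "duplicate ordered edges")
    if (!object@selfLoopsAdded && any(e[, 1] == e[, 2]))
      msg <- c(msg, "unexpected self loops")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellGraph from an ordered edge list
#'
#' @param nNodes number of cells.
#' @param edges 2-column matrix of ordered (source, target) index pairs.
#' @param selfLoopsAdded logical, see class docs.
#' @return A \linkS4class{CellGraph}.
#' @export
CellGraph <- function(nNodes, edges = matrix(integer(0), 0, 2),
                      selfLoopsAdded = FALSE) {
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("source", "target")))
  new("CellGraph", nNodes = as.integer(nNodes), edges = edges,
      selfLoopsAdded = selfLoopsAdded)
}

#' EdgeSplit: train/test partition of spatial contacts with test negatives
#'
#' The partition is over undirected contacts (both orientations of a contact
#' land on the same side); orientations are expanded, so `trainPos` and
#' `testPos` are ordered pairs. `testNeg` holds ordered pairs of distinct,
#' non-adjacent cells, matched in count to `testPos`.
#'
#' @slot trainPos,testPos,testNeg 2-column integer matrices of ordered pairs.
#' @slot testFraction numeric in (0,1).
#' @slot seed integer seed used for the split.
#' @export
setClass("EdgeSplit",
  representation(trainPos = "matrix", testPos = "matrix", testNeg = "matrix",
                 testFraction = "numeric", seed = "integer"))

setValidity("EdgeSplit", function(object) {
  msg <- character(0)
  if (object@testFraction <= 0 || object@testFraction >= 1)
    msg <- c(msg, "testFraction must be in (0,1)")
  for (nm in c("trainPos", "testPos", "testNeg"))
    if (ncol(slot(object, nm)) != 2L) msg <- c(msg, paste(nm, "not 2-column"))
  if (length(msg)) msg else TRUE
})

#' NormalizedAdjacency: degree-weighted message-passing operator
#'
#' Stores the normalised adjacency
#' \eqn{\hat A = (\tilde D^+)^{-\beta} \tilde A (\tilde D^-)^{-\alpha}}
#' where \eqn{\tilde A} is the (optionally self-loop augmented) adjacency and
#' \eqn{\tilde D^+ , \tilde D^-} its out-/in-degree diagonal matrices.
#'
#' @slot Ahat sparse Matrix, N x N, all entries finite.
#' @slot alpha,beta numeric degree exponents.
#' @slot selfLoopsAdded logical, whether I was added before normalisation.
#' @export
setClass("NormalizedAdjacency",
  representation(Ahat = "Matrix", alpha = "numeric", beta = "numeric",
                 selfLoopsAdded = "logical"))

#' DigaeModel: directed graph autoencoder weights and latent codes
#'
#' Two-layer encoder weights for the sender (S) and receiver (T) channels,
#' either one global set (homogeneous) or one set per cell type
#' (heterogeneous), plus the latent codes cached after training and the
#' normalised adjacency used for message passing.
#'
#' @slot mode "homogeneous" or "heterogeneous".
#' @slot weights list with elements WS0, WT0 (input -> hidden) and WS1, WT1
#'   (hidden -> latent); in heterogeneous mode each element is a named list of
#'   per-type matrices.
#' @slot typeLevels character; cell-type levels (heterogeneous mode).
#' @slot ZS,ZT numeric matrices N x latent (sender / receiver codes).
#' @slot Ahat the \linkS4class{NormalizedAdjacency} used in training.
#' @slot hyper list of hyperparameters (lr, epochs, hidden, latent, alpha,
#'   beta, seed, input widths).
#' @slot lossTrace numeric per-epoch training loss.
#' @export
setClass("DigaeModel",
  representation(mode = "character", weights = "list", typeLevels = "character",
                 ZS = "matrix", ZT = "matrix", Ahat = "NormalizedAdjacency",
                 hyper = "list", lossTrace = "numeric"))

#' ReconstructionResult: dense edge probabilities and thresholded edges
#'
#' @slot probs numeric N x N matrix, entries strictly in (0,1);
#'   `probs[i, j]` is the probability of a directed edge i -> j.
#' @slot threshold numeric in (0,1).
#' @slot edges 2-column integer matrix of predicted directed edges
#'   (`probs >= threshold`, self pairs excluded).
#' @slot metrics list of optional evaluation records.
#' @export
setClass("ReconstructionResult",
  representation(probs = "matrix", threshold = "numeric", edges = "matrix",
                 metrics = "list"))

setValidity("ReconstructionResult", function(object) {
  msg <- character(0)
  p <- object@probs
  if (any(p <= 0) || any(p >= 1)) msg <- c(msg, "probs must lie in (0,1)")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must be in (0,1)")
  if (length(msg)) msg else TRUE
})
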