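# Accessors and show methods.

#' @rdname SpatialDataset-class
#' @param object,x a SpatialDataset
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname SpatialDataset-class
#' @export
setMethod("exprMatrix", "SpatialDataset", function(x) x@exprs)

#' @rdname SpatialDataset-class
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname SpatialDataset-class
#' @export
setMethod("spatialCoords", "SpatialDataset", function(x) x@coords)

#' @rdname SpatialDataset-class
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname SpatialDataset-class
#' @export
setMethod("cellTypes", "SpatialDataset", function(x)
  if (length(x@cellTypes)) x@cellTypes else NULL)

#' @rdname SpatialDataset-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname SpatialDataset-class
#' @export
setMethod("nCells", "SpatialDataset", function(x) nrow(x@exprs))

#' @rdname SpatialDataset-class
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname SpatialDataset-class
#' @export
setMethod("nGenes", "SpatialDataset", function(x) ncol(x@exprs))

#' @rdname SpatialDataset-class
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname SpatialDataset-class
#' @export
setMethod("cellIds", "SpatialDataset", function(x) rownames(x@exprs))

#' @rdname SpatialDataset-class
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname SpatialDataset-class
#' @export
setMethod("geneNames", "SpatialDataset", function(x) colnames(x@exprs))

setMethod("show", "SpatialDataset", function(object) {
  cat("SpatialDataset:", nrow(object@exprs), "cells x",
      ncol(object@exprs), "genes\n")
  if (length(object@cellTypes))
    cat("  cell types:", paste(levels(factor(object@cellTypes)),
                               collapse = ", "), "\n")
  cat("  coordinate range: x [", paste(signif(range(object@coords[, 1]), 4),
      collapse = ", "), "], y [", paste(signif(range(object@coords[, 2]), 4),
      collapse = ", "), "]\n")
})

#' @rdname CellGraph-class
#' @param x,object a CellGraph
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname CellGraph-class
#' @export
setMethod("nNodes", "CellGraph", function(x) x@nNodes)

#' @rdname CellGraph-class
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname CellGraph-class
#' @export
setMethod("edgeMatrix", "CellGraph", function(x) x@edges)

#' Undirected contacts of a cell graph
#'
#' Collapses the symmetric ordered edge list to unique pairs with
#' source < target.
#'
#' @param x a \linkS4class{CellGraph}.
#' @return 2-column integer matrix of contacts.
#' @export
setGeneric("undirectedContacts", function(x)
  standardGeneric("undirectedContacts"))

#' @rdname undirectedContacts
#' @export
setMethod("undirectedContacts", "CellGraph", function(x) {
  p <- .undirectedPairs(x@edges)
  storage.mode(p) <- "integer"
  p
})

#' Sparse adjacency matrix of a cell graph
#'
#' @param x a \linkS4class{CellGraph}.
#' @param selfLoops add the identity (the augmented adjacency
#'   \eqn{\tilde A = A + I}).
#' @return a sparse dgCMatrix.
#' @export
setGeneric("adjacencyMatrix", function(x, selfLoops = FALSE)
  standardGeneric("adjacencyMatrix"))

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "CellGraph", function(x, selfLoops = FALSE) {
  n <- x@nNodes
  A <- Matrix::sparseMatrix(i = x@edges[, 1], j = x@edges[, 2], x = 1,
                            dims = c(n, n))
  if (selfLoops) A <- A + Matrix::Diagonal(n)
  A
})

#' Out- and in-degrees of the (augmented) adjacency
#'
#' @param x a \linkS4class{CellGraph}.
#' @param selfLoops augment with self loops before counting.
#' @return list with numeric vectors `out` (row sums of \eqn{\tilde A}) and
#'   `in` (column sums).
#' @export
graphDegrees <- function(x, selfLoops = FALSE) {
  A <- adjacencyMatrix(x, selfLoops = selfLoops)
  list(out = Matrix::rowSums(A), `in` = Matrix::colSums(A))
}

setMethod("show", "CellGraph", function(object) {
  nc <- nrow(.undirectedPairs(object@edges))
  cat("CellGraph:", object@nNodes, "cells,", nrow(object@edges),
      "directed edges (", nc, "undirected contacts )\n")
})

setMethod("show", "EdgeSplit", function(object) {
  cat("EdgeSplit:", nrow(object@trainPos), "train /", nrow(object@testPos),
      "test positive edges,", nrow(object@testNeg), "test negatives",
      sprintf("(test fraction %.2f, seed %d)\n",
              object@testFraction, object@seed))
})

#' @rdname EdgeSplit-class
#' @param x an EdgeSplit
#' @param which one of "trainPos", "testPos", "testNeg"
#' @return 2-column integer matrix of ordered pairs.
#' @export
splitPairs <- function(x, which = c("trainPos", "testPos", "testNeg")) {
  slot(x, match.arg(which))
}

setMethod("show", "NormalizedAdjacency", function(object) {
  cat(sprintf(
    "NormalizedAdjacency: %d x %d, alpha = %g, beta = %g, self loops %s\n",
    nrow(object@Ahat), ncol(object@Ahat), object@alpha, object@beta,
    if (object@selfLoopsAdded) "added" else "not added"))
})

#' @rdname NormalizedAdjacency-class
#' @param x a NormalizedAdjacency
#' @export
ahatMatrix <- function(x) x@Ahat

#' Latent sender/receiver codes of a trained model
#'
#' @param x a \linkS4class{DigaeModel}.
#' @return list with matrices `ZS` and `ZT`.
#' @export
latentCodes <- function(x) list(ZS = x@ZS, ZT = x@ZT)

#' @rdname DigaeModel-class
#' @param x a DigaeModel
#' @export
modelWeights <- function(x) x@weights

#' @rdname DigaeModel-class
#' @export
lossTrace <- function(x) x@lossTrace

setMethod("show", "DigaeModel", function(object) {
  cat("DigaeModel (", object@mode, "): input",
      paste(object@hyper$inputDims, collapse = "/"), "-> hidden",
      object@hyper$hidden, "-> latent", object@hyper$latent, "\n")
  if (length(object@lossTrace))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                length(object@lossTrace),
                object@lossTrace[length(object@lossTrace)]))
})

#' @rdname ReconstructionResult-class
#' @param x a ReconstructionResult
#' @export
edgeProbabilities <- function(x) x@probs

#' @rdname ReconstructionResult-class
#' @export
predictedEdges <- function(x) x@edges

setMethod("show", "ReconstructionResult", function(object) {
  cat(sprintf(
    "ReconstructionResult: %d x %d probabilities, %d edges at threshold %g\n",
    nrow(object@probs), ncol(object@probs), nrow(object@edges),
    object@threshold))
})
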