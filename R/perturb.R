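# Robustness perturbations of expression and graph inputs, plus
# ligand/receptor restricted initialisation. All operations are pure
# (inputs unmodified) and deterministic under a fixed seed.

#' Multiplicative log2-normal expression noise
#'
#' Each entry is multiplied by \eqn{2^r} with \eqn{r \sim N(0, \sigma)}
#' drawn independently per entry, i.e. fold-change noise that is Gaussian
#' after log2 transformation. Zeros stay exactly zero.
#'
#' @param X non-negative expression matrix.
#' @param sigma noise level (sigma >= 0; 0 returns X unchanged).
#' @param seed integer seed.
#' @return the noisy matrix.
#' @export
addNoise <- function(X, sigma, seed = 0) {
  if (sigma < 0) stop("config error: sigma must be >= 0")
  if (sigma == 0) return(X)
  withSeed(seed, X * 2^matrix(stats::rnorm(length(X), 0, sigma),
                              nrow(X), ncol(X)))
}

#' Randomly remove spatial contacts
#'
#' Removal is sampled over undirected contacts (both orientations of a
#' contact are removed together). The removed contacts are returned, with
#' both orientations expanded, as held-out positives, together with an equal
#' number of sampled non-adjacent ordered pairs as matched negatives.
#'
#' @param graph a \linkS4class{CellGraph}.
#' @param fraction fraction of contacts to remove, in [0,1); the removed
#'   count is `round(fraction * n_contacts)` (round-half-even).
#' @param seed integer seed.
#' @return list: `graph` (reduced \linkS4class{CellGraph}), `removed`
#'   (undirected contact matrix), `removedPairs` (both orientations),
#'   `negatives` (matched ordered non-adjacent pairs).
#' @export
removeEdges <- function(graph, fraction, seed = 0) {
  if (fraction < 0 || fraction >= 1)
    stop("config error: fraction must be in [0,1)")
  contacts <- undirectedContacts(graph)
  nc <- nrow(contacts)
  nRemove <- round(fraction * nc)
  if (nRemove == 0) {
    return(list(graph = graph,
                removed = contacts[0, , drop = FALSE],
                removedPairs = matrix(integer(0), 0, 2),
                negatives = matrix(integer(0), 0, 2)))
  }
  withSeed(seed, {
    idx <- sample.int(nc, nRemove)
    removed <- contacts[idx, , drop = FALSE]
    kept <- contacts[-idx, , drop = FALSE]
    reduced <- CellGraph(nNodes(graph), .bothOrientations(kept))
    removedPairs <- .bothOrientations(removed)
    negatives <- sampleNegativeEdges(graph, nrow(removedPairs))
    list(graph = reduced, removed = removed, removedPairs = removedPairs,
         negatives = negatives)
  })
}

#' Drop whole gene columns at random
#'
#' @param X expression matrix.
#' @param fraction fraction of genes to remove, in [0,1); the dropped count
#'   is `round(fraction * n_genes)` (round-half-even) and at least one gene
#'   must survive.
#' @param seed integer seed.
#' @return list: `X` (reduced matrix, surviving columns bitwise equal to
#'   the originals), `kept` (sorted surviving column indices).
#' @export
dropoutGenes <- function(X, fraction, seed = 0) {
  if (fraction < 0 || fraction >= 1)
    stop("config error: fraction must be in [0,1)")
  M <- ncol(X)
  nDrop <- round(fraction * M)
  if (nDrop >= M) stop("config error: all genes would be removed")
  if (nDrop == 0) return(list(X = X, kept = seq_len(M)))
  withSeed(seed, {
    dropIdx <- sample.int(M, nDrop)
    kept <- sort(setdiff(seq_len(M), dropIdx))
    list(X = X[, kept, drop = FALSE], kept = kept)
  })
}

#' Set a fraction of non-zero entries to zero
#'
#' Exactly `round(fraction * n_nonzero)` non-zero entries are chosen
#' uniformly without replacement and set to zero; existing zeros are
#' untouched.
#'
#' @param X expression matrix.
#' @param fraction fraction of non-zero entries to zero, in [0,1).
#' @param seed integer seed.
#' @return the sparsified matrix.
#' @export
dropoutValues <- function(X, fraction, seed = 0) {
  if (fraction < 0 || fraction >= 1)
    stop("config error: fraction must be in [0,1)")
  nz <- which(X != 0)
  nDrop <- round(fraction * length(nz))
  if (nDrop == 0) return(X)
  withSeed(seed, {
    X[nz[sample.int(length(nz), nDrop)]] <- 0
    X
  })
}

#' Ligand/receptor restricted encoder initialisation
#'
#' Builds the sender input S0 from the expression of the (unique) ligand
#' genes and the receiver input T0 from the (unique) receptor genes of a
#' ligand-receptor table, optionally restricted to one category. The two
#' matrices may differ in width; \code{\link{trainDigae}} sizes first-layer
#' weights per side. Gene matching is case-sensitive exact match unless
#' `caseFold` is set.
#'
#' @param dataset a \linkS4class{SpatialDataset}.
#' @param lrTable data.frame with columns ligand, receptor, category (see
#'   \code{\link{readLRTable}}).
#' @param categoryFilter optional single category ("Cell-Cell Contact",
#'   "Secreted Signaling" or "ECM").
#' @param caseFold match gene symbols case-insensitively.
#' @return list: `S0`, `T0` (expression submatrices), `ligands`,
#'   `receptors` (column manifests), `missing` (table genes absent from the
#'   dataset).
#' @export
lrInitialize <- function(dataset, lrTable, categoryFilter = NULL,
                         caseFold = FALSE) {
  tab <- validateLRTable(lrTable)
  if (!is.null(categoryFilter)) {
    if (!categoryFilter %in% .LR_CATEGORIES)
      stop("unknown category filter: ", categoryFilter)
    tab <- tab[tab$category == categoryFilter, , drop = FALSE]
  }
  genes <- geneNames(dataset)
  key <- if (caseFold) toupper(genes) else genes
  lookup <- function(g) match(if (caseFold) toupper(g) else g, key)
  lig <- unique(tab$ligand)
  rec <- unique(tab$receptor)
  ligIdx <- lookup(lig); recIdx <- lookup(rec)
  missing <- c(lig[is.na(ligIdx)], rec[is.na(recIdx)])
  ligIdx <- ligIdx[!is.na(ligIdx)]
  recIdx <- recIdx[!is.na(recIdx)]
  if (!length(ligIdx) || !length(recIdx))
    stop("empty-panel error: no ",
         if (!length(ligIdx)) "ligand" else "receptor",
         " genes found in the dataset; missing: ",
         paste(unique(missing), collapse = ", "))
  X <- exprMatrix(dataset)
  list(S0 = X[, ligIdx, drop = FALSE], T0 = X[, recIdx, drop = FALSE],
       ligands = genes[ligIdx], receptors = genes[recIdx],
       missing = unique(missing))
}
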