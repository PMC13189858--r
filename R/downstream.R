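# Downstream biology on the reconstructed network: cell-type interaction
# enrichment, gene and ligand-receptor permutation sensitivity, grouped
# network export.

#' Permutation enrichment of cell-type interactions
#'
#' Counts directed edges per ordered type pair (including within-type pairs)
#' and compares each observed count to a null distribution built by
#' permuting the cell-type labels over nodes with the edge set fixed
#' (degree structure exactly preserved). The empirical p-value uses the
#' add-one convention p = (1 + #\{null >= observed\}) / (1 + nPerm), so the
#' smallest attainable p is 1/(nPerm + 1).
#'
#' @param edges 2-column ordered edge matrix, or a
#'   \linkS4class{ReconstructionResult}.
#' @param cellTypes per-node type labels (no missing values).
#' @param nPerm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame of class "EnrichmentResult" with columns type_a,
#'   type_b, observed, null_mean, null_sd, p_value; attributes nPerm, seed.
#' @export
celltypeEnrichment <- function(edges, cellTypes, nPerm = 1000, seed = 0) {
  if (methods::is(edges, "ReconstructionResult")) edges <- predictedEdges(edges)
  if (anyNA(cellTypes)) stop("validation error: untyped node")
  if (nPerm < 1) stop("nPerm must be >= 1")
  types <- factor(cellTypes)
  lev <- levels(types)
  K <- length(lev)
  if (nrow(edges) && max(edges) > length(types))
    stop("validation error: edge endpoint without a type")
  countPairs <- function(lab) {
    tab <- table(factor(lab[edges[, 1]], levels = lev),
                 factor(lab[edges[, 2]], levels = lev))
    as.vector(tab)  # column-major: (type_a, type_b) over lev x lev
  }
  obs <- countPairs(types)
  withSeed(seed, {
    exceed <- numeric(K * K)
    nullSum <- numeric(K * K)
    nullSq <- numeric(K * K)
    for (p in seq_len(nPerm)) {
      cnt <- countPairs(sample(types))
      exceed <- exceed + (cnt >= obs)
      nullSum <- nullSum + cnt
      nullSq <- nullSq + cnt^2
    }
    nullMean <- nullSum / nPerm
    nullVar <- pmax(nullSq / nPerm - nullMean^2, 0)
    res <- data.frame(
      type_a = rep(lev, times = K), type_b = rep(lev, each = K),
      observed = obs, null_mean = nullMean,
      null_sd = sqrt(nullVar * nPerm / max(nPerm - 1, 1)),
      p_value = (1 + exceed) / (1 + nPerm))
    attr(res, "nPerm") <- nPerm
    attr(res, "seed") <- seed
    class(res) <- c("EnrichmentResult", "data.frame")
    res
  })
}

# Shared core: frozen-model shuffle-and-rescore for a set of gene columns.
# Returns the per-repeat delta AUROC (baseline minus shuffled).
.shuffleRescore <- function(model, dataset, split, geneIdx, nRepeats, seed,
                            baselineAuroc) {
  X <- exprMatrix(dataset)
  types <- if (model@mode == "heterogeneous") cellTypes(dataset) else NULL
  pos <- splitPairs(split, "testPos")
  neg <- splitPairs(split, "testNeg")
  labels <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  pairs <- rbind(pos, neg)
  deltas <- vapply(seq_len(nRepeats), function(r) {
    Xs <- X
    withSeed(deriveSeed(seed, r), {
      for (g in geneIdx) Xs[, g] <- Xs[sample.int(nrow(Xs)), g]
    })
    Z <- modelEncode(model, Xs, Xs, cellTypes = types)
    sc <- scoreEdgePairs(Z, pairs)
    baselineAuroc - evaluateLinks(sc, labels)$auroc
  }, numeric(1))
  deltas
}

.baselineAuroc <- function(model, split) {
  evaluateSplit(model, split)$auroc
}

#' Permutation sensitivity score of one gene
#'
#' Shuffles the gene's expression column across cells, re-scores the fixed
#' held-out split with the frozen trained model, and records
#' \eqn{\Delta}AUROC = baseline AUROC - shuffled AUROC per repeat (positive
#' means the gene matters). The mean over repeats is the sensitivity score.
#' A constant gene is unaffected by shuffling and scores exactly 0.
#'
#' @param model a trained \linkS4class{DigaeModel} (trained on the full
#'   expression matrix with S0 = T0 = X).
#' @param dataset the \linkS4class{SpatialDataset} the model was trained on.
#' @param split the \linkS4class{EdgeSplit} whose test pairs are re-scored.
#' @param gene gene name or column index.
#' @param nRepeats shuffle repeats (default 30).
#' @param seed integer seed; repeats use derived seeds.
#' @return list: `mean`, `sd` (0 with `sdDefined = FALSE` when
#'   nRepeats = 1), `deltas`, `baselineAuroc`.
#' @export
geneSensitivity <- function(model, dataset, split, gene, nRepeats = 30,
                            seed = 0) {
  gidx <- if (is.character(gene)) match(gene, geneNames(dataset))
          else as.integer(gene)
  if (is.na(gidx) || gidx < 1 || gidx > nGenes(dataset))
    stop("lookup error: unknown gene ", gene)
  base <- .baselineAuroc(model, split)
  deltas <- .shuffleRescore(model, dataset, split, gidx, nRepeats,
                            deriveSeed(seed, gidx), base)
  list(mean = mean(deltas),
       sd = if (nRepeats > 1) stats::sd(deltas) else 0,
       sdDefined = nRepeats > 1,
       deltas = deltas, baselineAuroc = base)
}

#' Permutation sensitivity scores for many genes
#'
#' Applies \code{\link{geneSensitivity}} per gene with per-gene derived
#' seeds (so results do not depend on iteration order) and returns a report
#' sorted by decreasing mean \eqn{\Delta}AUROC.
#'
#' @param model,dataset,split as in \code{\link{geneSensitivity}}.
#' @param genes gene names or indices (default: all genes).
#' @param nRepeats shuffle repeats per gene.
#' @param seed base integer seed.
#' @param topN optionally keep only the top N rows (with a warning when N
#'   exceeds the number of genes scored).
#' @return data.frame of class "SensitivityReport": feature,
#'   mean_delta_auroc, sd_delta_auroc, n_repeats; attributes baselineAuroc
#'   and deltas (per-gene repeat values).
#' @export
allGeneSensitivity <- function(model, dataset, split, genes = NULL,
                               nRepeats = 30, seed = 0, topN = NULL) {
  if (is.null(genes)) genes <- geneNames(dataset)
  base <- .baselineAuroc(model, split)
  gidxAll <- if (is.character(genes)) match(genes, geneNames(dataset))
             else as.integer(genes)
  if (anyNA(gidxAll)) stop("lookup error: unknown gene(s)")
  allDeltas <- lapply(gidxAll, function(g)
    .shuffleRescore(model, dataset, split, g, nRepeats,
                    deriveSeed(seed, g), base))
  res <- data.frame(
    feature = geneNames(dataset)[gidxAll],
    mean_delta_auroc = vapply(allDeltas, mean, numeric(1)),
    sd_delta_auroc = if (nRepeats > 1)
      vapply(allDeltas, stats::sd, numeric(1)) else 0,
    n_repeats = nRepeats)
  names(allDeltas) <- res$feature
  ord <- order(res$mean_delta_auroc, decreasing = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(topN)) {
    if (topN > nrow(res))
      warning("topN = ", topN, " exceeds the ", nrow(res), " genes scored")
    res <- utils::head(res, topN)
  }
  attr(res, "baselineAuroc") <- base
  attr(res, "deltas") <- allDeltas
  class(res) <- c("SensitivityReport", "data.frame")
  res
}

#' Permutation sensitivity of ligand-receptor pairs
#'
#' Pairs are first filtered to those co-expressed in the relevant cells:
#' the ligand must be non-zero in at least `coExprFraction` of the source
#' cells and the receptor in at least that fraction of the target cells
#' (all cells when no `cellTypePair` is given). Each retained pair is then
#' scored like a gene, except both columns are shuffled in the same repeat
#' (independent permutations per column).
#'
#' @param model,dataset,split as in \code{\link{geneSensitivity}}.
#' @param lrTable ligand-receptor data.frame (see \code{\link{readLRTable}}).
#' @param cellTypePair optional character vector c(source_type, target_type)
#'   restricting the co-expression filter.
#' @param nRepeats shuffle repeats per pair (default 30).
#' @param seed base integer seed.
#' @param coExprFraction co-expression filter threshold (fraction of cells
#'   with non-zero expression), default 0.1.
#' @return data.frame of class "SensitivityReport": feature ("LIG->REC"),
#'   ligand, receptor, category, mean_delta_auroc, sd_delta_auroc,
#'   n_repeats; attribute `diagnostics` lists excluded pairs and why.
#' @export
lrPairSensitivity <- function(model, dataset, split, lrTable,
                              cellTypePair = NULL, nRepeats = 30, seed = 0,
                              coExprFraction = 0.1) {
  tab <- validateLRTable(lrTable)
  X <- exprMatrix(dataset)
  genes <- geneNames(dataset)
  srcCells <- seq_len(nrow(X)); tgtCells <- srcCells
  if (!is.null(cellTypePair)) {
    types <- cellTypes(dataset)
    if (is.null(types)) stop("cellTypePair given but dataset has no types")
    srcCells <- which(types == cellTypePair[1])
    tgtCells <- which(types == cellTypePair[2])
  }
  diag <- data.frame(ligand = character(0), receptor = character(0),
                     reason = character(0))
  keep <- logical(nrow(tab))
  ligIdx <- match(tab$ligand, genes)
  recIdx <- match(tab$receptor, genes)
  for (i in seq_len(nrow(tab))) {
    if (is.na(ligIdx[i]) || is.na(recIdx[i])) {
      diag <- rbind(diag, data.frame(ligand = tab$ligand[i],
                                     receptor = tab$receptor[i],
                                     reason = "gene absent from dataset"))
      next
    }
    coL <- mean(X[srcCells, ligIdx[i]] > 0)
    coR <- mean(X[tgtCells, recIdx[i]] > 0)
    if (coL < coExprFraction || coR < coExprFraction) {
      diag <- rbind(diag, data.frame(
        ligand = tab$ligand[i], receptor = tab$receptor[i],
        reason = sprintf("below co-expression threshold (%.2f / %.2f)",
                         coL, coR)))
      next
    }
    keep[i] <- TRUE
  }
  if (!any(keep))
    stop("empty-result error: no ligand-receptor pair survives the ",
         "co-expression filter (", nrow(diag), " excluded)")
  tab <- tab[keep, , drop = FALSE]
  ligIdx <- ligIdx[keep]; recIdx <- recIdx[keep]
  base <- .baselineAuroc(model, split)
  allDeltas <- lapply(seq_len(nrow(tab)), function(i)
    .shuffleRescore(model, dataset, split, c(ligIdx[i], recIdx[i]),
                    nRepeats, deriveSeed(seed, ligIdx[i], recIdx[i]), base))
  res <- data.frame(
    feature = paste0(tab$ligand, "->", tab$receptor),
    ligand = tab$ligand, receptor = tab$receptor, category = tab$category,
    mean_delta_auroc = vapply(allDeltas, mean, numeric(1)),
    sd_delta_auroc = if (nRepeats > 1)
      vapply(allDeltas, stats::sd, numeric(1)) else 0,
    n_repeats = nRepeats)
  res <- res[order(res$mean_delta_auroc, decreasing = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "baselineAuroc") <- base
  attr(res, "diagnostics") <- diag
  class(res) <- c("SensitivityReport", "data.frame")
  res
}

#' Export the enriched cell-type interaction network
#'
#' One row per ordered type pair whose enrichment p-value passes `alpha`
#' (inclusive comparison, p <= alpha, so `alpha = 1` exports every pair):
#' source type, target type, directed edge count, p-value — the table behind
#' arrow-diagram renderings of enriched communication between cell types.
#'
#' @param edges predicted directed edges (matrix or
#'   \linkS4class{ReconstructionResult}).
#' @param cellTypes per-node type labels.
#' @param enrichment an EnrichmentResult computed on the same edges.
#' @param alpha significance cutoff (default 0.05).
#' @return data.frame: source_type, target_type, edge_count, p_value.
#' @export
exportGroupedNetwork <- function(edges, cellTypes, enrichment,
                                 alpha = 0.05) {
  if (methods::is(edges, "ReconstructionResult")) edges <- predictedEdges(edges)
  keep <- enrichment$p_value <= alpha
  out <- data.frame(source_type = enrichment$type_a[keep],
                    target_type = enrichment$type_b[keep],
                    edge_count = enrichment$observed[keep],
                    p_value = enrichment$p_value[keep])
  rownames(out) <- NULL
  out
}
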