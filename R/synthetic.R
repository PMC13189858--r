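# Seed-reproducible synthetic spatial transcriptomics with planted spatial,
# type and directional structure. Defaults define the package's reference
# study conditions; the methods vignette records the rationale.

#' Configuration for the synthetic data generator
#'
#' @param nCells number of cells.
#' @param nGenes number of genes.
#' @param nTypes number of cell types.
#' @param domainSize side length of the square tissue (arbitrary units).
#' @param typeSpatialClustering in [0,1]: 0 assigns types uniformly at
#'   random, 1 makes types occupy disjoint spatial slabs.
#' @param signalGenesPerType number of marker genes elevated per type
#'   (disjoint blocks; `signalGenesPerType * nTypes <= nGenes`).
#' @param neighborCoupling strength of the latent factor shared by the two
#'   endpoints of each spatial contact; this is what makes adjacency
#'   learnable from expression.
#' @param ligandBlock,receptorBlock disjoint gene index sets carrying the
#'   planted directional sender-to-receiver signal; set both to `integer(0)`
#'   to disable.
#' @param senderType 1-based index of the designated sender cell type.
#' @param directionalEffect additive (pre-softplus) boost of ligand genes in
#'   sender cells and receptor genes in their graph successors.
#' @param signatureGeneBlock gene index set carrying the shared edge
#'   factors, i.e. the spatially autocorrelated genes through which
#'   adjacency is learnable from expression — the planted ground truth for
#'   sensitivity scoring. In real panels only a minority of genes shows
#'   strong spatial autocorrelation, so the default is a block of 10.
#'   When empty, the factors load on every gene outside the noise and
#'   ligand/receptor blocks instead. Disjoint from the other blocks.
#' @param noiseGeneBlock gene index set receiving no structure at all (no
#'   type program, no neighbour coupling, no directional signal): pure
#'   baseline-plus-noise genes, emulating the uninformative fraction of a
#'   real gene panel and providing negative controls for sensitivity
#'   scoring. Must be disjoint from marker and ligand/receptor blocks.
#' @param dropoutRate per-entry Bernoulli zeroing probability in [0,1).
#' @param noiseSd standard deviation of additive Gaussian noise
#'   (pre-softplus).
#' @param countMode if TRUE, draw negative-binomial counts with the softplus
#'   values as means (size = 10) instead of returning real values.
#' @param seed integer seed; all outputs are fully determined by it.
#' @return a validated list of class "SyntheticConfig".
#' @export
syntheticConfig <- function(nCells = 1000, nGenes = 100, nTypes = 3,
                            domainSize = 100,
                            typeSpatialClustering = 0.8,
                            signalGenesPerType = 10,
                            neighborCoupling = 2,
                            ligandBlock =
                              if (nGenes >= 12) (nGenes - 9):(nGenes - 5)
                              else integer(0),
                            receptorBlock =
                              if (nGenes >= 12) (nGenes - 4):nGenes
                              else integer(0),
                            senderType = 1,
                            directionalEffect = 3,
                            signatureGeneBlock =
                              if (nGenes >= 60)
                                (nGenes - 29):(nGenes - 20) else integer(0),
                            noiseGeneBlock =
                              if (nGenes >= 50)
                                (nGenes - 19):(nGenes - 10) else integer(0),
                            dropoutRate = 0.1,
                            noiseSd = 0.3,
                            countMode = FALSE,
                            seed = 0) {
  cfg <- list(nCells = as.integer(nCells), nGenes = as.integer(nGenes),
              nTypes = as.integer(nTypes), domainSize = domainSize,
              typeSpatialClustering = typeSpatialClustering,
              signalGenesPerType = as.integer(signalGenesPerType),
              neighborCoupling = neighborCoupling,
              ligandBlock = as.integer(ligandBlock),
              receptorBlock = as.integer(receptorBlock),
              senderType = as.integer(senderType),
              directionalEffect = directionalEffect,
              signatureGeneBlock = as.integer(signatureGeneBlock),
              noiseGeneBlock = as.integer(noiseGeneBlock),
              dropoutRate = dropoutRate, noiseSd = noiseSd,
              countMode = isTRUE(countMode), seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  validateSyntheticConfig(cfg)
}

#' @rdname syntheticConfig
#' @param config a SyntheticConfig to validate.
#' @export
validateSyntheticConfig <- function(config) {
  with(config, {
    if (nCells < 1 || nGenes < 1 || nTypes < 1 || domainSize <= 0)
      stop("invalid config: sizes must be positive")
    if (nTypes > nCells)
      stop("invalid config: more cell types than cells")
    if (typeSpatialClustering < 0 || typeSpatialClustering > 1)
      stop("invalid config: typeSpatialClustering must be in [0,1]")
    if (signalGenesPerType < 0 ||
        signalGenesPerType * nTypes > nGenes)
      stop("invalid config: signalGenesPerType * nTypes exceeds nGenes")
    if (length(intersect(ligandBlock, receptorBlock)))
      stop("invalid config: ligand and receptor blocks overlap")
    if (length(c(ligandBlock, receptorBlock)) &&
        (min(c(ligandBlock, receptorBlock)) < 1 ||
         max(c(ligandBlock, receptorBlock)) > nGenes))
      stop("invalid config: ligand/receptor block indices out of range")
    if (length(noiseGeneBlock)) {
      if (min(noiseGeneBlock) < 1 || max(noiseGeneBlock) > nGenes)
        stop("invalid config: noiseGeneBlock indices out of range")
      if (length(intersect(noiseGeneBlock, c(ligandBlock, receptorBlock))))
        stop("invalid config: noiseGeneBlock overlaps ligand/receptor block")
      if (signalGenesPerType > 0 &&
          length(intersect(noiseGeneBlock,
                           seq_len(signalGenesPerType * nTypes))))
        stop("invalid config: noiseGeneBlock overlaps marker blocks")
    }
    if (length(signatureGeneBlock)) {
      if (min(signatureGeneBlock) < 1 || max(signatureGeneBlock) > nGenes)
        stop("invalid config: signatureGeneBlock indices out of range")
      if (length(intersect(signatureGeneBlock,
                           c(ligandBlock, receptorBlock, noiseGeneBlock))))
        stop("invalid config: signatureGeneBlock overlaps another block")
    }
    if (dropoutRate < 0 || dropoutRate >= 1)
      stop("invalid config: dropoutRate must be in [0,1)")
    if (noiseSd < 0) stop("invalid config: noiseSd must be >= 0")
    if (senderType < 1 || senderType > nTypes)
      stop("invalid config: senderType out of range")
  })
  config
}

#' Generate a spatial layout of typed cells
#'
#' Coordinates are i.i.d. uniform on the square, then relaxed by one Lloyd
#' step (Monte Carlo form: each cell moves to the centroid of the uniform
#' sample points nearest to it) for even spacing. Each cell's type mixes a
#' uniform random draw with a spatial-slab draw: with probability
#' `typeSpatialClustering` the type is the cell's x-quantile slab, otherwise
#' uniform over types.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return data.frame with columns cell_id, x, y, cell_type (types are
#'   "type_1".."type_K").
#' @export
generateLayout <- function(config) {
  validateSyntheticConfig(config)
  withSeed(config$seed, {
    n <- config$nCells
    L <- config$domainSize
    co <- cbind(stats::runif(n, 0, L), stats::runif(n, 0, L))
    if (n >= 4) {
      # one Lloyd relaxation step via dense uniform reference samples
      m <- min(20L * n, 50000L)
      samp <- cbind(stats::runif(m, 0, L), stats::runif(m, 0, L))
      km <- suppressWarnings(
        stats::kmeans(samp, centers = co, iter.max = 1,
                      algorithm = "Lloyd"))
      moved <- km$centers
      ok <- is.finite(moved[, 1]) & is.finite(moved[, 2])
      co[ok, ] <- moved[ok, ]
    }
    # spatial slab by x-quantile; balanced occupancy by construction
    slab <- ceiling(rank(co[, 1], ties.method = "first") /
                      n * config$nTypes)
    slab[slab < 1] <- 1L
    useSlab <- stats::runif(n) < config$typeSpatialClustering
    types <- ifelse(useSlab, slab,
                    sample.int(config$nTypes, n, replace = TRUE))
    data.frame(cell_id = paste0("cell_", seq_len(n)),
               x = co[, 1], y = co[, 2],
               cell_type = paste0("type_", types),
               stringsAsFactors = FALSE)
  })
}

#' Generate expression with planted spatial and directional structure
#'
#' The pre-activation signal for cell i is the sum of its type's program
#' (baseline plus elevated marker block), `neighborCoupling` times the sum of
#' per-contact latent factor vectors shared with each spatial neighbour, the
#' directional block (ligand genes up in sender-type cells, receptor genes up
#' in their graph successors) and N(0, noiseSd) noise; softplus maps it to
#' non-negative values and entries are then zeroed with probability
#' `dropoutRate`.
#'
#' @param layout output of \code{\link{generateLayout}}.
#' @param graph a \linkS4class{CellGraph} built on the same layout.
#' @param config the \code{\link{syntheticConfig}}.
#' @return list with `X` (nCells x nGenes matrix) and `truth` (list with
#'   senderCells, receiverCells, directedEdges, ligandBlock, receptorBlock,
#'   signalGenes per type).
#' @export
generateExpression <- function(layout, graph, config) {
  validateSyntheticConfig(config)
  n <- config$nCells
  M <- config$nGenes
  if (nrow(layout) != n || nNodes(graph) != n)
    stop("dimension error: layout/graph/config cell counts disagree")
  withSeed(deriveSeed(config$seed, 2L), {
    typeIdx <- as.integer(factor(layout$cell_type,
                                 levels = paste0("type_",
                                                 seq_len(config$nTypes))))
    # type programs: baseline 1, marker block +2
    programs <- matrix(1, config$nTypes, M)
    signalGenes <- vector("list", config$nTypes)
    if (config$signalGenesPerType > 0) {
      for (t in seq_len(config$nTypes)) {
        gidx <- ((t - 1) * config$signalGenesPerType + 1):
          (t * config$signalGenesPerType)
        programs[t, gidx] <- programs[t, gidx] + 2
        signalGenes[[t]] <- gidx
      }
    }
    pre <- programs[typeIdx, , drop = FALSE]
    # shared per-contact latent factors: both endpoints receive the same
    # random gene-loading vector, so adjacent cells correlate
    contacts <- undirectedContacts(graph)
    if (nrow(contacts) > 0 && config$neighborCoupling > 0) {
      coupled <- if (length(config$signatureGeneBlock))
        config$signatureGeneBlock
      else setdiff(seq_len(M), c(config$noiseGeneBlock,
                                 config$ligandBlock, config$receptorBlock))
      fac <- matrix(stats::rnorm(nrow(contacts) * M, sd = 1 / sqrt(3)),
                    nrow(contacts), M)
      fac[, setdiff(seq_len(M), coupled)] <- 0
      incid <- Matrix::sparseMatrix(
        i = c(contacts[, 1], contacts[, 2]),
        j = rep(seq_len(nrow(contacts)), 2), x = 1,
        dims = c(n, nrow(contacts)))
      pre <- pre + config$neighborCoupling * as.matrix(incid %*% fac)
    }
    # planted directional signal
    senders <- integer(0); receivers <- integer(0)
    directed <- matrix(integer(0), 0, 2)
    if (length(config$ligandBlock) && length(config$receptorBlock)) {
      senders <- which(typeIdx == config$senderType)
      e <- edgeMatrix(graph)
      sel <- e[, 1] %in% senders & !(e[, 2] %in% senders)
      directed <- e[sel, , drop = FALSE]
      receivers <- sort(unique(directed[, 2]))
      if (length(senders))
        pre[senders, config$ligandBlock] <-
          pre[senders, config$ligandBlock] + config$directionalEffect
      if (length(receivers))
        pre[receivers, config$receptorBlock] <-
          pre[receivers, config$receptorBlock] + config$directionalEffect
    }
    if (config$noiseSd > 0)
      pre <- pre + matrix(stats::rnorm(n * M, sd = config$noiseSd), n, M)
    X <- softplus(pre)
    if (config$countMode)
      X <- matrix(stats::rnbinom(n * M, mu = X, size = 10), n, M)
    if (config$dropoutRate > 0) {
      drop <- matrix(stats::runif(n * M) < config$dropoutRate, n, M)
      X[drop] <- 0
    }
    rownames(X) <- layout$cell_id
    colnames(X) <- paste0("gene_", seq_len(M))
    list(X = X,
         truth = list(senderCells = senders, receiverCells = receivers,
                      directedEdges = directed,
                      ligandBlock = config$ligandBlock,
                      receptorBlock = config$receptorBlock,
                      signatureGeneBlock = config$signatureGeneBlock,
                      noiseGeneBlock = config$noiseGeneBlock,
                      signalGenes = signalGenes))
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: layout, contact graph (k = 3 within the derived
#' distance threshold), expression, and the planted-truth record.
#'
#' @param config a \code{\link{syntheticConfig}} (defaults used if missing).
#' @param k,percentile contact graph parameters, see
#'   \code{\link{buildAdjacency}}.
#' @return list with `dataset` (\linkS4class{SpatialDataset}), `graph`
#'   (\linkS4class{CellGraph}), `truth` (planted-truth record) and `config`.
#' @examples
#' sim <- generateDataset(syntheticConfig(nCells = 60, nGenes = 20, seed = 1))
#' sim$dataset
#' @export
generateDataset <- function(config = syntheticConfig(), k = 3,
                            percentile = 95) {
  validateSyntheticConfig(config)
  layout <- generateLayout(config)
  co <- as.matrix(layout[, c("x", "y")])
  thr <- computeDistanceThreshold(co, k = k, percentile = percentile)
  graph <- buildAdjacency(co, thr, k = k)
  ex <- generateExpression(layout, graph, config)
  ds <- SpatialDataset(ex$X, co, cellTypes = layout$cell_type)
  list(dataset = ds, graph = graph, truth = ex$truth, config = config)
}

#' Write a synthetic dataset and its truth record to disk
#'
#' @param sim result of \code{\link{generateDataset}}.
#' @param dir output directory.
#' @param format expression format, "csv" or "mtx".
#' @return invisibly, paths written.
#' @export
writeSyntheticDataset <- function(sim, dir, format = "csv") {
  paths <- writeDataset(sim$dataset, dir, format = format)
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, tp, auto_unbox = FALSE, digits = NA)
  gp <- file.path(dir, "graph.tsv")
  writeEdgeList(edgeMatrix(sim$graph), gp, ids = cellIds(sim$dataset))
  invisible(c(paths, tp, gp))
}
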