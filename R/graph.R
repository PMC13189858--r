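# Spatial contact graph construction and edge splitting.

#' Distance threshold for direct cell contact
#'
#' Direct-contact candidates are a cell's k nearest neighbours, but only
#' within a distance cutoff derived from the tissue itself: the given
#' percentile of the distribution of every cell's k-th nearest-neighbour
#' distance. At the default (k = 3, 95th percentile) almost all cells keep
#' their three nearest neighbours while outlying, isolated cells are not
#' force-connected across gaps.
#'
#' @param coords N x 2 coordinate matrix (N >= 2, Euclidean units).
#' @param k neighbour rank whose distance distribution is summarised.
#' @param percentile percentile (0-100) of the k-NN distance distribution.
#' @return positive scalar distance threshold.
#' @examples
#' co <- cbind(0:3, 0)  # collinear, spacing 1
#' computeDistanceThreshold(co, k = 1)  # 1
#' @export
computeDistanceThreshold <- function(coords, k = 3, percentile = 95) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L)
    stop("insufficient data: need at least 2 cells to derive a threshold")
  k <- min(as.integer(k), nrow(coords) - 1L)
  kd <- .knn(coords, k)$dist[, k]
  as.numeric(stats::quantile(kd, percentile / 100, type = 7))
}

#' Build the spatial cell adjacency graph
#'
#' For each cell the candidate partners are its k nearest neighbours at
#' distance <= threshold; the union over cells of all such pairs, with both
#' orientations emitted, is the contact edge set (a cell pair is connected if
#' either member selects the other). No self loops are added at this stage.
#' Nearest-neighbour ties are broken by lower cell index.
#'
#' @param coords N x 2 coordinate matrix.
#' @param threshold positive contact distance cutoff, typically from
#'   \code{\link{computeDistanceThreshold}}.
#' @param k number of nearest neighbours considered per cell.
#' @return A \linkS4class{CellGraph} with a symmetric ordered edge set.
#' @examples
#' g <- buildAdjacency(cbind(0:3, 0), threshold = 1.5, k = 3)
#' undirectedContacts(g)  # (1,2) (2,3) (3,4)
#' @export
buildAdjacency <- function(coords, threshold, k = 3) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(threshold > 0, k >= 1)
  if (n < 2L) return(CellGraph(n))
  nn <- .knn(coords, k)
  src <- rep(seq_len(n), each = ncol(nn$index))
  tgt <- as.vector(t(nn$index))
  d <- as.vector(t(nn$dist))
  keep <- d <= threshold
  contacts <- .undirectedPairs(cbind(src[keep], tgt[keep]))
  if (nrow(contacts) == 0L) return(CellGraph(n))
  ord <- order(contacts[, 1], contacts[, 2])
  CellGraph(n, .bothOrientations(contacts[ord, , drop = FALSE]))
}

#' Split contacts into train/test sets with sampled test negatives
#'
#' Splitting is performed on undirected contacts, so both orientations of a
#' contact always land on the same side; orientations are then expanded into
#' ordered pairs. Test negatives are ordered pairs of distinct cells that are
#' not adjacent in the graph, rejection-sampled uniformly without
#' replacement, matched in count to the ordered test positives.
#'
#' @param graph a \linkS4class{CellGraph} with at least 10 undirected
#'   contacts.
#' @param testFraction fraction of contacts held out for testing (default
#'   0.1, i.e. a 90/10 train/test split).
#' @param seed integer seed; the split is deterministic given the seed.
#' @param nNeg number of test negatives; defaults to the number of ordered
#'   test positives.
#' @return An \linkS4class{EdgeSplit}.
#' @export
splitEdges <- function(graph, testFraction = 0.1, seed = 0, nNeg = NULL) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0,1)")
  contacts <- undirectedContacts(graph)
  nc <- nrow(contacts)
  if (nc < 10L)
    stop("insufficient edges: need at least 10 undirected contacts to split")
  withSeed(seed, {
    nTest <- max(1L, round(nc * testFraction))
    testIdx <- sample.int(nc, nTest)
    testC <- contacts[testIdx, , drop = FALSE]
    trainC <- contacts[-testIdx, , drop = FALSE]
    testPos <- .bothOrientations(testC)
    if (is.null(nNeg)) nNeg <- nrow(testPos)
    testNeg <- sampleNegativeEdges(graph, nNeg)
    new("EdgeSplit",
        trainPos = .bothOrientations(trainC), testPos = testPos,
        testNeg = testNeg, testFraction = testFraction,
        seed = as.integer(seed))
  })
}

#' Sample ordered non-adjacent cell pairs
#'
#' Uniform rejection sampling of ordered pairs of distinct cells absent from
#' the graph's edge set (and from `exclude`), without replacement. Uses the
#' current RNG stream; seed management is the caller's job.
#'
#' @param graph a \linkS4class{CellGraph} supplying the positive edge set.
#' @param n number of negatives required.
#' @param exclude optional extra 2-column matrix of ordered pairs to avoid.
#' @return 2-column integer matrix of ordered pairs.
#' @export
sampleNegativeEdges <- function(graph, n, exclude = NULL) {
  N <- nNodes(graph)
  if (as.double(N) * (N - 1) < n + nrow(graph@edges))
    stop("graph too dense to sample ", n, " distinct negatives")
  forbidden <- .pairKey(graph@edges, N)
  if (!is.null(exclude) && nrow(exclude))
    forbidden <- c(forbidden, .pairKey(exclude, N))
  # self pairs forbidden too
  diagKeys <- (as.double(seq_len(N)) - 1) * N + seq_len(N)
  forbidden <- c(forbidden, diagKeys)
  out <- double(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.3) + 8L
    i <- sample.int(N, m, replace = TRUE)
    j <- sample.int(N, m, replace = TRUE)
    keys <- (as.double(i) - 1) * N + j
    ok <- !(keys %in% forbidden) & !(keys %in% out) & !duplicated(keys)
    out <- c(out, keys[ok])
  }
  out <- out[seq_len(n)]
  cbind(as.integer((out - 1) %/% N + 1), as.integer((out - 1) %% N + 1))
}
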