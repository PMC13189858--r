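# Link-prediction metrics and the robustness scan protocol.

#' Link-prediction metrics for scored edges
#'
#' AUROC is computed as the midrank Wilcoxon statistic (tied scores receive
#' midranks, so a constant score vector yields exactly 0.5); AUPRC by step
#' integration of the precision-recall curve (average-precision form,
#' descending unique score thresholds); F1 and accuracy at the stated
#' threshold with an inclusive comparison (score >= threshold is a
#' positive call).
#'
#' @param scores numeric score/probability vector.
#' @param labels binary labels (0/1), same length.
#' @param threshold classification threshold for F1/accuracy.
#' @return one-row data.frame: auroc, auprc, f1, accuracy, n_pos, n_neg,
#'   threshold_used.
#' @examples
#' evaluateLinks(c(.9, .8, .1, .2), c(1, 1, 0, 0))
#' @export
evaluateLinks <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("undefined-metric error: both classes must be present")
  r <- rank(scores)  # midranks for ties
  auroc <- (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  # AUPRC: group tied scores, descending thresholds
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tpCum <- cumsum(y); nCum <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tpCum[last]; n <- nCum[last]
  prec <- tp / n
  rec <- tp / nPos
  auprc <- sum(diff(c(0, rec)) * prec)
  pred <- as.integer(scores >= threshold)
  tpos <- sum(pred == 1 & labels == 1)
  f1 <- if (tpos == 0) 0 else {
    precn <- tpos / sum(pred == 1)
    recn <- tpos / nPos
    2 * precn * recn / (precn + recn)
  }
  acc <- mean(pred == labels)
  data.frame(auroc = auroc, auprc = auprc, f1 = f1, accuracy = acc,
             n_pos = nPos, n_neg = nNeg, threshold_used = threshold)
}

#' Evaluate a trained model on its held-out split
#'
#' Scores the ordered test positives and test negatives with the asymmetric
#' decoder and summarises them with \code{\link{evaluateLinks}}.
#'
#' @param model a trained \linkS4class{DigaeModel} or a list with ZS, ZT.
#' @param split an \linkS4class{EdgeSplit}, or a list with elements
#'   `pos` and `neg` (2-column ordered pair matrices).
#' @param threshold classification threshold.
#' @return one-row metrics data.frame (see \code{\link{evaluateLinks}}).
#' @export
evaluateSplit <- function(model, split, threshold = 0.5) {
  if (methods::is(split, "EdgeSplit")) {
    pos <- splitPairs(split, "testPos")
    neg <- splitPairs(split, "testNeg")
  } else {
    pos <- split$pos; neg <- split$neg
  }
  scores <- scoreEdgePairs(model, rbind(pos, neg))
  evaluateLinks(scores, c(rep(1, nrow(pos)), rep(0, nrow(neg))), threshold)
}

# Welch t-test p-value with the degenerate-tie convention: two groups with
# no variability and equal means are an exact tie, reported as p = 1.
.welchP <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
           error = function(e) 1)
}

#' Robustness scan: perturb, retrain, evaluate, test significance
#'
#' For each perturbation level the pipeline perturb -> train -> evaluate is
#' run `nReps` times with distinct derived seeds; a two-sided Welch t-test
#' compares each level's AUROC replicates with the unperturbed baseline
#' replicates, and levels with p < 0.05 are flagged as significant
#' degradation. Perturbation kinds: "noise" (multiplicative log2-normal
#' expression noise, level = sigma), "edges" (fraction of contacts removed;
#' the removed contacts become the held-out positives), "genes" (fraction of
#' gene columns dropped), "values" (fraction of non-zero entries zeroed).
#'
#' @param dataset a \linkS4class{SpatialDataset}.
#' @param graph the spatial \linkS4class{CellGraph} for the dataset.
#' @param kind one of "noise", "edges", "genes", "values".
#' @param levels ascending perturbation magnitudes (level 0 = baseline
#'   conditions).
#' @param nReps replicates per level (>= 2 for the t-test).
#' @param baseSeed base seed; per-replicate seeds derive from it.
#' @param testFraction held-out fraction for the baseline split.
#' @param trainArgs list of extra arguments passed to
#'   \code{\link{trainDigae}} (e.g. epochs, hidden).
#' @return list of class "RobustnessScan": `perRep` (level, rep, seed,
#'   auroc, auprc, f1, accuracy), `summary` (level, mean_auroc, sd_auroc,
#'   p_value, significant), `kind`, `baseline` (baseline replicate rows).
#' @export
robustnessScan <- function(dataset, graph,
                           kind = c("noise", "edges", "genes", "values"),
                           levels, nReps = 5, baseSeed = 0,
                           testFraction = 0.1, trainArgs = list()) {
  kind <- match.arg(kind)
  if (is.unsorted(levels)) stop("levels must be sorted ascending")
  if (nReps < 2) stop("nReps must be >= 2 for the t-test")
  kindId <- match(kind, c("noise", "edges", "genes", "values"))

  runOne <- function(level, rep) {
    seed <- deriveSeed(baseSeed, kindId, match(level, levels), rep)
    if (kind == "edges" && level > 0) {
      rem <- removeEdges(graph, level, seed = seed)
      split <- new("EdgeSplit",
                   trainPos = edgeMatrix(rem$graph),
                   testPos = rem$removedPairs, testNeg = rem$negatives,
                   testFraction = level, seed = as.integer(seed))
      ds <- dataset
    } else {
      split <- splitEdges(graph, testFraction, seed = seed)
      X <- exprMatrix(dataset)
      if (level > 0) {
        X <- switch(kind,
          noise = addNoise(X, level, seed = deriveSeed(seed, 1L)),
          genes = dropoutGenes(X, level, seed = deriveSeed(seed, 1L))$X,
          values = dropoutValues(X, level, seed = deriveSeed(seed, 1L)),
          edges = X)
      }
      ds <- SpatialDataset(X, spatialCoords(dataset),
                           cellTypes = cellTypes(dataset))
    }
    model <- do.call(trainDigae,
                     c(list(dataset = ds, split = split, seed = seed),
                       trainArgs))
    cbind(data.frame(level = level, rep = rep, seed = seed),
          evaluateSplit(model, split)[, c("auroc", "auprc", "f1",
                                          "accuracy")])
  }

  baseline <- do.call(rbind, lapply(seq_len(nReps), function(r)
    runOne(0, r)))
  perRep <- baseline
  for (lv in setdiff(levels, 0)) {
    perRep <- rbind(perRep,
                    do.call(rbind, lapply(seq_len(nReps), function(r)
                      runOne(lv, r))))
  }
  if (!0 %in% levels) perRep <- perRep[perRep$level %in% levels |
                                         perRep$level == 0, ]
  summ <- do.call(rbind, lapply(levels, function(lv) {
    v <- perRep$auroc[perRep$level == lv]
    p <- if (lv == 0) 1 else .welchP(v, baseline$auroc)
    data.frame(level = lv, mean_auroc = mean(v), sd_auroc = stats::sd(v),
               p_value = p, significant = p < 0.05)
  }))
  structure(list(perRep = perRep, summary = summ, kind = kind,
                 baseline = baseline, nReps = nReps, baseSeed = baseSeed),
            class = "RobustnessScan")
}

#' @export
print.RobustnessScan <- function(x, ...) {
  cat("RobustnessScan (", x$kind, "), ", x$nReps, " reps per level\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write robustness scan outputs as tidy CSVs
#'
#' @param scan a RobustnessScan.
#' @param dir output directory; writes `scan_<kind>_replicates.csv` and
#'   `scan_<kind>_summary.csv`.
#' @return invisibly, the two paths.
#' @export
writeScan <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0("scan_", scan$kind, "_replicates.csv"))
  p2 <- file.path(dir, paste0("scan_", scan$kind, "_summary.csv"))
  utils::write.csv(scan$perRep, p1, row.names = FALSE)
  utils::write.csv(scan$summary, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
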