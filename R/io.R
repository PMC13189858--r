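# Reading and writing datasets, edge lists and ligand-receptor tables.

.readDelim <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

# Expression from CSV/TSV (cells x genes, optional leading cell id column)
# or MatrixMarket .mtx with <stem>_cells.txt / <stem>_genes.txt sidecars.
.readExpression <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    X <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    cellsFile <- paste0(stem, "_cells.txt")
    genesFile <- paste0(stem, "_genes.txt")
    rownames(X) <- if (file.exists(cellsFile)) readLines(cellsFile)
                   else paste0("cell_", seq_len(nrow(X)))
    colnames(X) <- if (file.exists(genesFile)) readLines(genesFile)
                   else paste0("gene_", seq_len(ncol(X)))
    return(X)
  }
  if (!grepl("\\.(csv|tsv|txt)$", path, ignore.case = TRUE))
    stop("unknown expression format: ", path,
         " (expected .csv, .tsv, .txt or .mtx)")
  df <- .readDelim(path)
  if (ncol(df) > 1 && !is.numeric(df[[1]])) {
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else {
    ids <- paste0("cell_", seq_len(nrow(df)))
  }
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  rownames(X) <- ids
  X
}

#' Load a spatial transcriptomics dataset from files
#'
#' Expression is read from CSV/TSV (cells x genes; a non-numeric first column
#' is taken as cell ids) or MatrixMarket (`.mtx`, with optional
#' `<stem>_cells.txt` / `<stem>_genes.txt` name sidecars). Coordinates and
#' types are CSV/TSV with columns (cell_id, x, y) and (cell_id, cell_type);
#' when both files carry cell ids rows are aligned by id, otherwise by row
#' order.
#'
#' @param expressionPath path to the expression matrix.
#' @param coordsPath path to the coordinates table.
#' @param typesPath optional path to the cell type table.
#' @return A \linkS4class{SpatialDataset}.
#' @export
loadDataset <- function(expressionPath, coordsPath, typesPath = NULL) {
  X <- .readExpression(expressionPath)
  co <- .readDelim(coordsPath)
  idCol <- which(!vapply(co, is.numeric, logical(1)))[1]
  if (!is.na(idCol)) {
    coIds <- as.character(co[[idCol]])
    co <- co[, -idCol, drop = FALSE]
  } else coIds <- NULL
  if (ncol(co) < 2) stop("coordinates file needs x and y columns")
  co <- as.matrix(co[, 1:2])
  if (nrow(co) != nrow(X))
    stop("alignment error: expression has ", nrow(X), " cells but ",
         "coordinates have ", nrow(co), " rows")
  if (!is.null(coIds) && all(rownames(X) %in% coIds)) {
    co <- co[match(rownames(X), coIds), , drop = FALSE]
  }
  if (anyNA(co)) stop("validation error: NaN in coordinates")
  types <- NULL
  if (!is.null(typesPath)) {
    tt <- .readDelim(typesPath)
    if (nrow(tt) != nrow(X))
      stop("alignment error: types file has ", nrow(tt), " rows but ",
           "expression has ", nrow(X), " cells")
    typeCol <- ncol(tt)
    if (ncol(tt) >= 2 && all(rownames(X) %in% as.character(tt[[1]]))) {
      tt <- tt[match(rownames(X), as.character(tt[[1]])), , drop = FALSE]
    }
    types <- as.character(tt[[typeCol]])
  }
  SpatialDataset(X, co, cellTypes = types)
}

#' Write a SpatialDataset to plain-text files
#'
#' Writes `expression.csv` (or `expression.mtx` plus name sidecars),
#' `coords.csv` (cell_id,x,y) and, when labels exist, `types.csv`
#' (cell_id,cell_type) into `dir`.
#'
#' @param dataset a \linkS4class{SpatialDataset}.
#' @param dir output directory (created if needed).
#' @param format "csv" or "mtx" for the expression matrix.
#' @return invisibly, the vector of paths written.
#' @export
writeDataset <- function(dataset, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- exprMatrix(dataset)
  paths <- character(0)
  if (format == "csv") {
    p <- file.path(dir, "expression.csv")
    utils::write.csv(data.frame(cell_id = rownames(X), X,
                                check.names = FALSE),
                     p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  } else {
    p <- file.path(dir, "expression.mtx")
    Matrix::writeMM(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                "generalMatrix"), p)
    writeLines(rownames(X), file.path(dir, "expression_cells.txt"))
    writeLines(colnames(X), file.path(dir, "expression_genes.txt"))
    paths <- c(paths, p, file.path(dir, "expression_cells.txt"),
               file.path(dir, "expression_genes.txt"))
  }
  co <- spatialCoords(dataset)
  pco <- file.path(dir, "coords.csv")
  utils::write.csv(data.frame(cell_id = rownames(X), x = co[, 1],
                              y = co[, 2]),
                   pco, row.names = FALSE, quote = FALSE)
  paths <- c(paths, pco)
  if (!is.null(cellTypes(dataset))) {
    pt <- file.path(dir, "types.csv")
    utils::write.csv(data.frame(cell_id = rownames(X),
                                cell_type = cellTypes(dataset)),
                     pt, row.names = FALSE, quote = FALSE)
    paths <- c(paths, pt)
  }
  invisible(paths)
}

#' Write a directed edge list as TSV
#'
#' @param edges 2-column matrix of node indices, or a
#'   \linkS4class{ReconstructionResult}.
#' @param path output path; columns source_id, target_id and, when
#'   probabilities are available, probability.
#' @param ids optional cell id vector used to translate indices.
#' @return invisibly, `path`.
#' @export
writeEdgeList <- function(edges, path, ids = NULL) {
  prob <- NULL
  if (methods::is(edges, "ReconstructionResult")) {
    res <- edges
    edges <- predictedEdges(res)
    prob <- edgeProbabilities(res)[edges]
  }
  src <- edges[, 1]; tgt <- edges[, 2]
  if (!is.null(ids)) { src <- ids[src]; tgt <- ids[tgt] }
  df <- data.frame(source_id = src, target_id = tgt)
  if (!is.null(prob)) df$probability <- prob
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.LR_CATEGORIES <- c("Cell-Cell Contact", "Secreted Signaling", "ECM")

#' Read a ligand-receptor pair table
#'
#' Expects a CSV/TSV with columns `ligand`, `receptor`, `category` (a
#' CellChatDB-style export). Categories must be one of "Cell-Cell Contact",
#' "Secreted Signaling", "ECM"; the spelled-out "Extra Cellular Matrix" (and
#' "ECM-Receptor") are normalised to "ECM". Duplicate pairs are dropped.
#'
#' @param path path to the table.
#' @return data.frame with columns ligand, receptor, category.
#' @export
readLRTable <- function(path) {
  df <- .readDelim(path)
  names(df) <- tolower(names(df))
  need <- c("ligand", "receptor", "category")
  if (!all(need %in% names(df)))
    stop("ligand-receptor table must have columns ligand, receptor, category")
  df <- df[, need]
  df$category[df$category %in%
                c("Extra Cellular Matrix", "Extracellular Matrix",
                  "ECM-Receptor")] <- "ECM"
  validateLRTable(df)
}

#' Validate a ligand-receptor table held in memory
#'
#' @param df data.frame with columns ligand, receptor, category.
#' @return the validated, de-duplicated data.frame.
#' @export
validateLRTable <- function(df) {
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor)) ||
      anyNA(df$ligand) || anyNA(df$receptor))
    stop("ligand-receptor table contains empty gene names")
  bad <- setdiff(unique(df$category), .LR_CATEGORIES)
  if (length(bad))
    stop("unknown ligand-receptor categories: ", paste(bad, collapse = ", "))
  df[!duplicated(df[, c("ligand", "receptor")]), , drop = FALSE]
}
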