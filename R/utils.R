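# Internal numerical and RNG helpers.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so package functions taking a
#' `seed` argument are pure with respect to the caller's random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a child seed from a base seed and stream counters
#'
#' A single base seed fans out to per-stage, per-replicate seeds through a
#' fixed affine map modulo a Mersenne prime, so one number reproduces a whole
#' scan. Collisions between distinct counter tuples are possible in principle
#' but astronomically unlikely at the scales used here.
#'
#' @param base integer base seed.
#' @param ... integer stream counters (stage index, level index, replicate).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(base, ...) {
  counters <- c(...)
  s <- as.double(base) %% 2147483647
  for (ct in counters) {
    s <- (s * 48271 + as.double(ct) * 16807 + 12345) %% 2147483647
  }
  as.integer(s %% 2147483645 + 1)
}

# Pairwise k-nearest-neighbour distances, blockwise to bound memory.
# Returns list(dist = N x k matrix, index = N x k matrix). Ties broken by
# lower index (stable sort on distance then index).
.knn <- function(coords, k, block = 1024L) {
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points for nearest-neighbour distances")
  k <- min(k, n - 1L)
  di <- matrix(NA_real_, n, k)
  ix <- matrix(NA_integer_, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    # squared distances block x n
    d2 <- outer(coords[rows, 1], coords[, 1], "-")^2 +
      outer(coords[rows, 2], coords[, 2], "-")^2
    for (r in seq_along(rows)) {
      i <- rows[r]
      d <- d2[r, ]
      d[i] <- Inf
      ord <- order(d, seq_len(n))[seq_len(k)]
      ix[i, ] <- ord
      di[i, ] <- sqrt(d[ord])
    }
  }
  list(dist = di, index = ix)
}

# Canonical undirected form of an ordered pair matrix: unique rows with i < j.
.undirectedPairs <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(matrix(integer(0), 0, 2))
  }
  lo <- pmin(pairs[, 1], pairs[, 2])
  hi <- pmax(pairs[, 1], pairs[, 2])
  keep <- !duplicated(cbind(lo, hi)) & lo != hi
  cbind(lo[keep], hi[keep])
}

# Both orientations of undirected contact pairs.
.bothOrientations <- function(contacts) {
  rbind(contacts, contacts[, 2:1, drop = FALSE])
}

# Encode ordered pairs as scalar keys for fast membership tests.
.pairKey <- function(pairs, n) {
  (as.double(pairs[, 1]) - 1) * n + as.double(pairs[, 2])
}
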