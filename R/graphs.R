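.graphMat <- function(g) {
  if (is(g, "SampleGraph")) relationMatrix(g) else as.matrix(g)
}

#' Gower distances for mixed covariates
#'
#' Classical Gower dissimilarity: the average over variables of a
#' per-variable term -- 0/1 mismatch for categorical variables
#' (character/factor/logical), absolute difference divided by the observed
#' range for numeric variables. Constant numeric variables contribute zero.
#'
#' @param covariates data.frame of sample covariates (e.g. sex and age),
#'   one row per sample, at least one column.
#' @return Symmetric n x n distance matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
gowerDistances <- function(covariates) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 1 || nrow(covariates) < 1)
    stop("covariate table must have at least one row and one column")
  n <- nrow(covariates)
  d <- matrix(0, n, n)
  for (col in covariates) {
    if (is.numeric(col)) {
      rng <- diff(range(col))
      if (rng > 0) d <- d + abs(outer(col, col, "-")) / rng
    } else {
      col <- as.character(col)
      d <- d + (outer(col, col, "!=")) * 1
    }
  }
  d <- d / ncol(covariates)
  dimnames(d) <- list(rownames(covariates), rownames(covariates))
  d
}

#' Aitchison (log-ratio) distances between compositions
#'
#' Euclidean distance between the clr-transformed rows of a composition
#' table.
#'
#' @param c a [CompositionTable-class].
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
logratioDistances <- function(c) {
  zc <- clrFeatures(c)
  as.matrix(stats::dist(zc))
}

#' k-nearest-neighbour relation graph
#'
#' Directed k-NN indicator `S[i, j] = 1` iff j is among the k nearest
#' neighbours of i (self excluded; distance ties broken toward the smaller
#' sample index), symmetrized as `R = (S + t(S)) / 2`, so entries are 0
#' (neither direction), 0.5 (one direction) or 1 (mutual).
#'
#' @param d symmetric distance matrix.
#' @param k number of neighbours, `1 <= k < n`.
#' @return A [SampleGraph-class].
#' @export
knnRelationGraph <- function(d, k = 5) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    nb <- order(di, seq_len(n))[seq_len(k)]
    S[i, nb] <- 1
  }
  r <- (S + t(S)) / 2
  dimnames(r) <- dimnames(d)
  SampleGraph(r)
}

#' Block graph from cluster labels
#'
#' `r[m, l] = 1` iff samples m and l carry the same label (m != l); the
#' exact relation structure of a clustered population.
#'
#' @param labels length-n vector of cluster labels.
#' @return A [SampleGraph-class] with binary entries.
#' @export
blockGraph <- function(labels) {
  if (!length(labels)) stop("labels must be nonempty")
  r <- outer(labels, labels, "==") * 1
  diag(r) <- 0
  SampleGraph(r)
}

#' Corrupt a binary graph elementwise
#'
#' Each upper-triangle element keeps its true value with probability `pr`
#' and is flipped (0 <-> 1) with probability `1 - pr`, independently; the
#' result is mirrored to the lower triangle, diagonal stays zero. Models an
#' imperfectly observed relation structure.
#'
#' @param g a binary [SampleGraph-class] (or matrix).
#' @param pr probability in (0, 1] of observing the true value.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A [SampleGraph-class].
#' @export
corruptGraph <- function(g, pr, seed = NULL) {
  r <- .graphMat(g)
  if (!all(r %in% c(0, 1))) stop("graph entries must be binary")
  if (pr <= 0 || pr > 1) stop("pr must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(r)
  u <- stats::runif(sum(ut))
  .applyCorruption(r, pr, u)
}

# deterministic core given the uniforms for the upper triangle
.applyCorruption <- function(r, pr, u) {
  ut <- upper.tri(r)
  vals <- r[ut]
  flip <- u >= pr
  vals[flip] <- 1 - vals[flip]
  out <- matrix(0, nrow(r), ncol(r), dimnames = dimnames(r))
  out[ut] <- vals
  out <- out + t(out)
  SampleGraph(out)
}

#' Read / write a sample graph
#'
#' Dense format: an n x n CSV with an id column and header (the dialect of
#' [writeCounts()]). Edge-list format: a 3-column TSV `i`, `j`, `weight`
#' (ids or 1-based indices); absent pairs are zero.
#'
#' @param path file path.
#' @param format `"dense"` or `"edgelist"`.
#' @param ids for `"edgelist"`, the full ordered sample id vector (needed to
#'   recover isolated samples).
#' @return A [SampleGraph-class] (`readSampleGraph`) or `path` invisibly.
#' @export
readSampleGraph <- function(path, format = c("dense", "edgelist"), ids = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    return(SampleGraph(as.matrix(df)))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(ids)) ids <- sort(unique(c(as.character(df[[1]]), as.character(df[[2]]))))
  r <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(df))) {
    i <- as.character(df[k, 1]); j <- as.character(df[k, 2])
    r[i, j] <- df[k, 3]; r[j, i] <- df[k, 3]
  }
  SampleGraph(r)
}

#' @rdname readSampleGraph
#' @param g a [SampleGraph-class] to write.
#' @export
writeSampleGraph <- function(g, path, format = c("dense", "edgelist")) {
  format <- match.arg(format)
  r <- .graphMat(g)
  if (format == "dense") {
    .writeIdMatrix(r, path, ",")
  } else {
    idx <- which(upper.tri(r) & r > 0, arr.ind = TRUE)
    df <- data.frame(i = rownames(r)[idx[, 1]], j = colnames(r)[idx[, 2]],
                     weight = r[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
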