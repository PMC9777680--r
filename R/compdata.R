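#' Read a count table from CSV/TSV
#'
#' Expects a header row of feature ids and a first column of sample ids
#' (samples x features). Row and column order are preserved.
#'
#' @param path file path.
#' @param fmt `"csv"` or `"tsv"`; default guessed from the file extension.
#' @return A [CountTable-class].
#' @seealso [writeCounts()], [countsToComposition()]
#' @export
loadCounts <- function(path, fmt = c("auto", "csv", "tsv")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (fmt == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  CountTable(m)
}

#' Write a count table to CSV/TSV
#'
#' Emits the same dialect [loadCounts()] reads (header of feature ids, first
#' column of sample ids).
#'
#' @param t a [CountTable-class].
#' @param path output file path.
#' @param fmt `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(t, path, fmt = c("auto", "csv", "tsv")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  sep <- if (fmt == "csv") "," else "\t"
  .writeIdMatrix(counts(t), path, sep)
  invisible(path)
}

.writeIdMatrix <- function(m, path, sep = ",", idHeader = "id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idHeader
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Convert counts to compositions with zero replacement
#'
#' Zero counts are replaced by `zeroReplacement` (a pseudo-count, by default
#' one), then each row is closed (divided by its sum) so that it lies on the
#' simplex and the log transform is defined everywhere.
#'
#' @param t a [CountTable-class].
#' @param zeroReplacement positive value substituted for zero counts.
#' @return A [CompositionTable-class]; rows sum to one.
#' @export
#' @examples
#' ct <- CountTable(matrix(c(0, 3, 2, 2), 2, 2, byrow = TRUE))
#' compositions(countsToComposition(ct))  # first row (0.25, 0.75)
countsToComposition <- function(t, zeroReplacement = 1) {
  stopifnot(zeroReplacement >= 0)
  m <- counts(t)
  m[m == 0] <- zeroReplacement
  rs <- rowSums(m)
  if (any(rs <= 0))
    stop("row(s) with zero total count and zeroReplacement = 0: ",
         paste(rownames(m)[rs <= 0], collapse = ", "))
  CompositionTable(m / rs)
}

#' Log-feature matrix of a composition table
#'
#' Elementwise natural logarithm, `z_ij = log x_ij`; the covariate matrix of
#' the log-contrast model.
#'
#' @param c a [CompositionTable-class].
#' @return An n x p numeric matrix with the same dimnames.
#' @export
logFeatures <- function(c) {
  x <- compositions(c)
  if (any(x <= 0)) stop("nonpositive composition entry")
  log(x)
}

#' Centered log-ratio (clr) transform
#'
#' `z_ij = log x_ij - mean_j log x_ij`; each output row sums to zero. The
#' clr maps the simplex to a zero-sum Euclidean subspace and underlies the
#' Aitchison (log-ratio) distance.
#'
#' @param c a [CompositionTable-class].
#' @return An n x p numeric matrix with zero row sums.
#' @export
clrFeatures <- function(c) {
  z <- logFeatures(c)
  z - rowMeans(z)
}

#' Agglomerate features by cophenetic distance on a phylogeny
#'
#' Single-linkage agglomerative clustering of the features on their pairwise
#' cophenetic (tree-path) distances; clusters merge while the linkage
#' distance is strictly below `threshold`. Counts of merged features are
#' summed and the merged feature keeps the lexicographically smallest member
#' id. Total count mass is conserved and the operation is idempotent.
#'
#' @param t a [CountTable-class].
#' @param tree an [ape::phylo] tree whose tip labels cover the feature ids.
#' @param threshold nonnegative cophenetic distance cut.
#' @return A [CountTable-class] with merged features, ordered by the first
#'   occurrence of each cluster in the original column order.
#' @export
aggregateByCophenetic <- function(t, tree, threshold = 0.5) {
  stopifnot(inherits(tree, "phylo"), threshold >= 0)
  m <- counts(t)
  feats <- colnames(m)
  missing <- setdiff(feats, tree$tip.label)
  if (length(missing))
    stop("features missing from tree: ", paste(missing, collapse = ", "))
  p <- length(feats)
  if (p == 1) return(t)
  d <- stats::cophenetic(tree)[feats, feats]
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  # strict '<': only merges whose single-linkage height is below the cut
  k <- p - sum(hc$height < threshold)
  grp <- stats::cutree(hc, k = k)
  first <- vapply(split(seq_len(p), grp), min, integer(1))
  ord <- order(first)                       # cluster order = first occurrence
  agg <- t(rowsum(t(m), group = grp))       # sums columns within clusters
  ids <- vapply(split(feats, grp), function(f) min(f), character(1))
  agg <- agg[, ord, drop = FALSE]
  colnames(agg) <- unname(ids[ord])
  rownames(agg) <- rownames(m)
  CountTable(agg)
}
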