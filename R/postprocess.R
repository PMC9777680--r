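#' Extract latent clusters from fused coefficient rows
#'
#' Two samples are linked when their coefficient vectors agree within `tol`
#' in the infinity norm; connected components of the resulting graph are
#' the latent clusters (so `tol = 0` gives exact-equality components).
#' Cluster labels are numbered by first occurrence.
#'
#' @param w n x p coefficient matrix (e.g. `coef(fit)`).
#' @param tol nonnegative fusion tolerance; the default matches the
#'   solver's convergence tolerance.
#' @return A [ClusterReport-class].
#' @export
extractFusedClusters <- function(w, tol = 1e-4) {
  w <- as.matrix(w)
  stopifnot(tol >= 0)
  n <- nrow(w)
  labels <- integer(n)
  nextLab <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      nextLab <- nextLab + 1L
      comp <- i
      frontier <- i
      while (length(frontier)) {
        cur <- frontier[1]
        frontier <- frontier[-1]
        if (labels[cur]) next
        labels[cur] <- nextLab
        rest <- which(labels == 0L)
        if (length(rest)) {
          diffs <- abs(w[rest, , drop = FALSE] -
                         matrix(w[cur, ], length(rest), ncol(w), byrow = TRUE))
          near <- rest[apply(diffs, 1, max) <= tol]
          frontier <- c(frontier, near)
        }
      }
    }
  }
  reps <- do.call(rbind, lapply(seq_len(nextLab), function(g)
    colMeans(w[labels == g, , drop = FALSE])))
  colnames(reps) <- colnames(w)
  new("ClusterReport", labels = labels, nClusters = nextLab,
      representatives = reps)
}

#' Threshold near-zero coefficients
#'
#' Entries with `|w_ij| < cutoff` are set to exactly zero; a feature is
#' retained when at least one sample keeps a nonzero coefficient for it.
#' Thresholding can break the exact zero-sum of constrained rows; the
#' result flags this rather than re-projecting.
#'
#' @param w n x p coefficient matrix.
#' @param cutoff nonnegative magnitude cutoff (default 0.05).
#' @return List with `w` (thresholded matrix), `retained` (character or
#'   integer vector of retained features) and `zeroSumBroken` (logical,
#'   TRUE when some thresholded row no longer sums to zero within 1e-8 of
#'   its original sum).
#' @export
thresholdCoefficients <- function(w, cutoff = 0.05) {
  w <- as.matrix(w)
  stopifnot(cutoff >= 0)
  wt <- w
  wt[abs(wt) < cutoff] <- 0
  keep <- apply(wt != 0, 2, any)
  retained <- if (!is.null(colnames(w))) colnames(w)[keep] else which(keep)
  list(w = wt,
       retained = retained,
       zeroSumBroken = any(abs(rowSums(wt) - rowSums(w)) > 1e-8))
}

#' Hierarchical grouping of coefficient vectors
#'
#' Agglomerative clustering of the coefficient rows (Ward linkage on
#' Euclidean distances by default), cut at `nGroups` clusters; used to
#' order and group samples for reporting and heatmaps.
#'
#' @param w n x p coefficient matrix.
#' @param nGroups number of groups, `1 <= nGroups <= n`.
#' @param linkage `hclust` agglomeration method.
#' @return Integer group labels (as from [stats::cutree()]).
#' @export
hierarchicalGroup <- function(w, nGroups = 5, linkage = "ward.D2") {
  w <- as.matrix(w)
  if (nGroups < 1 || nGroups > nrow(w))
    stop("nGroups must be between 1 and the number of samples")
  hc <- stats::hclust(stats::dist(w), method = linkage)
  stats::cutree(hc, k = nGroups)
}

#' Long-format export of a coefficient matrix
#'
#' Sample/feature/value triples, convenient for heatmap rendering.
#'
#' @param w n x p coefficient matrix with dimnames.
#' @return data.frame with columns `sample`, `feature`, `value`.
#' @export
coefficientsLong <- function(w) {
  w <- as.matrix(w)
  data.frame(sample = rep(rownames(w), times = ncol(w)),
             feature = rep(colnames(w), each = nrow(w)),
             value = as.vector(w), stringsAsFactors = FALSE)
}
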