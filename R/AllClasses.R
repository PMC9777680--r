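#' @importFrom methods new validObject setClass setValidity setMethod setGeneric show is slot
NULL

.checkIds <- function(ids, what) {
  if (anyDuplicated(ids)) return(sprintf("duplicated %s ids", what))
  if (any(!nzchar(ids))) return(sprintf("empty %s id", what))
  NULL
}

#' CountTable: a samples-by-features table of nonnegative counts
#'
#' Container for raw feature counts (e.g. OTU or ASV counts), with unique
#' sample and feature identifiers carried as the matrix dimnames.
#'
#' @slot counts numeric matrix, n samples x p features, nonnegative.
#' @export
setClass("CountTable", representation(counts = "matrix"))

setValidity("CountTable", function(object) {
  m <- object@counts
  msgs <- character()
  if (!is.numeric(m)) msgs <- c(msgs, "counts must be numeric")
  else {
    if (any(!is.finite(m))) msgs <- c(msgs, "counts must be finite")
    else if (any(m < 0)) msgs <- c(msgs, "counts must be nonnegative")
  }
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "counts must have sample (row) and feature (column) names")
  else
    msgs <- c(msgs, .checkIds(rownames(m), "sample"), .checkIds(colnames(m), "feature"))
  if (length(msgs)) msgs else TRUE
})

#' Construct a CountTable
#'
#' @param counts numeric matrix of nonnegative counts; if dimnames are
#'   missing, `sample_i` / `feature_j` ids are generated.
#' @return A [CountTable-class] object.
#' @export
#' @examples
#' CountTable(matrix(c(0, 3, 5, 2), 2, 2, byrow = TRUE))
CountTable <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("feature_", seq_len(ncol(counts)))
  new("CountTable", counts = counts)
}

#' CompositionTable: strictly positive compositions on the simplex
#'
#' Each row is a composition: strictly positive proportions summing to one.
#'
#' @slot x numeric matrix, n x p, rows on the open simplex.
#' @export
setClass("CompositionTable", representation(x = "matrix"))

setValidity("CompositionTable", function(object) {
  m <- object@x
  msgs <- character()
  if (any(!is.finite(m)) || any(m <= 0))
    msgs <- c(msgs, "compositions must be finite and strictly positive")
  else if (any(abs(rowSums(m) - 1) > 1e-8))
    msgs <- c(msgs, "composition rows must sum to 1")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "compositions must have sample and feature names")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CompositionTable
#'
#' @param x numeric matrix with strictly positive rows summing to one.
#' @return A [CompositionTable-class] object.
#' @export
CompositionTable <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  new("CompositionTable", x = x)
}

#' SampleGraph: symmetric nonnegative sample relation weights
#'
#' The relation matrix R with `r[m, l] >= 0` quantifying how strongly samples
#' m and l should share a regression model; zero diagonal. k-NN relation
#' graphs take values in {0, 0.5, 1}.
#'
#' @slot r numeric n x n matrix, symmetric, nonnegative, zero diagonal.
#' @export
setClass("SampleGraph", representation(r = "matrix"))

setValidity("SampleGraph", function(object) {
  m <- object@r
  msgs <- character()
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "relation matrix must be square")
  else {
    if (any(!is.finite(m)) || any(m < 0))
      msgs <- c(msgs, "relation weights must be finite and nonnegative")
    if (any(abs(m - t(m)) > 1e-10)) msgs <- c(msgs, "relation matrix must be symmetric")
    if (any(diag(m) != 0)) msgs <- c(msgs, "diagonal must be zero")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SampleGraph
#'
#' @param r symmetric nonnegative matrix with zero diagonal.
#' @return A [SampleGraph-class] object.
#' @export
SampleGraph <- function(r) {
  r <- as.matrix(r)
  if (is.null(rownames(r))) {
    ids <- colnames(r)
    if (is.null(ids)) ids <- paste0("sample_", seq_len(nrow(r)))
    dimnames(r) <- list(ids, ids)
  }
  new("SampleGraph", r = r)
}

#' SNLFit: fitted sparse network lasso model
#'
#' Result of [fitSparseNetwork()]. The reported coefficients are the sparse
#' ADMM copies `b_i` (one p-vector per sample); the raw `w_i` iterates are
#' kept for diagnostics. For a constrained fit every coefficient row sums to
#' zero within the convergence tolerance.
#'
#' @slot coefficients n x p matrix of per-sample coefficient vectors (b).
#' @slot w n x p matrix of raw primal iterates.
#' @slot yOffset centering offset subtracted from the response before fitting.
#' @slot zScale unit-SD covariate scaling (empty unless the fit used
#'   `standardize = TRUE`); predictions re-apply it to new covariates.
#' @slot lambda1,lambda2 regularization parameters used.
#' @slot constrained logical; whether the zero-sum constraint was enforced.
#' @slot iterations,converged ADMM iteration count and convergence flag.
#' @slot residuals named numeric of final primal residual norms.
#' @slot objective value of the penalized objective at the solution.
#' @export
setClass("SNLFit", representation(
  coefficients = "matrix", w = "matrix", yOffset = "numeric",
  zScale = "numeric",
  lambda1 = "numeric", lambda2 = "numeric", constrained = "logical",
  iterations = "integer", converged = "logical",
  residuals = "numeric", objective = "numeric"))

#' LassoFit: fitted compositional lasso baseline
#'
#' A single zero-sum coefficient vector shared by all samples.
#'
#' @slot coefficients length-p coefficient vector.
#' @slot yOffset response centering offset.
#' @slot lambda regularization parameter.
#' @slot iterations,converged ADMM iteration count and convergence flag.
#' @export
setClass("LassoFit", representation(
  coefficients = "numeric", yOffset = "numeric", lambda = "numeric",
  iterations = "integer", converged = "logical"))

#' SimulationData: one synthetic dataset from the three-cluster design
#'
#' @slot composition [CompositionTable-class] of the n simulated compositions.
#' @slot z n x p log-feature matrix.
#' @slot y length-n response.
#' @slot clusters integer cluster label per sample (1..3).
#' @slot trueCoefficients n x p matrix of the true per-sample coefficients.
#' @slot trueGraph,observedGraph [SampleGraph-class]: the exact block graph
#'   and its elementwise-corrupted version.
#' @slot trainIdx,validationIdx integer index split.
#' @slot config list of the generating parameters (p, sigma, pr, n, seed, ...).
#' @export
setClass("SimulationData", representation(
  composition = "CompositionTable", z = "matrix", y = "numeric",
  clusters = "integer", trueCoefficients = "matrix",
  trueGraph = "SampleGraph", observedGraph = "SampleGraph",
  trainIdx = "integer", validationIdx = "integer", config = "list"))

#' CVResult: grid-search cross-validation summary
#'
#' @slot grid data.frame of regularization points, one row per point.
#' @slot meanError,sdError mean and sd of the CV error per grid point.
#' @slot foldErrors matrix (grid points x folds) of per-fold errors.
#' @slot best integer row index of the selected point (minimal mean error,
#'   ties broken toward stronger regularization).
#' @slot K number of folds; @slot seed fold-assignment seed.
#' @export
setClass("CVResult", representation(
  grid = "data.frame", meanError = "numeric", sdError = "numeric",
  foldErrors = "matrix", best = "integer", K = "integer", seed = "integer"))

#' ClusterReport: latent clusters read off fused coefficients
#'
#' @slot labels integer cluster label per sample, in [1, nClusters].
#' @slot nClusters number of clusters found.
#' @slot representatives nClusters x p matrix; mean coefficient vector of the
#'   member samples of each cluster.
#' @export
setClass("ClusterReport", representation(
  labels = "integer", nClusters = "integer", representatives = "matrix"))
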