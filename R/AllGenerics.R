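#' Accessors for compnetlasso containers
#'
#' `counts()` returns the raw count matrix of a [CountTable-class];
#' `compositions()` the closed composition matrix of a
#' [CompositionTable-class]; `relationMatrix()` the dense relation matrix of
#' a [SampleGraph-class]; `sampleIds()` / `featureIds()` the identifiers.
#'
#' @param object a compnetlasso container object.
#' @return The underlying matrix or character vector of ids.
#' @name accessors
#' @aliases counts compositions relationMatrix sampleIds featureIds
#' @examples
#' ct <- CountTable(matrix(1:4, 2, 2))
#' counts(ct)
#' sampleIds(ct)
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("compositions", function(object) standardGeneric("compositions"))
#' @rdname accessors
#' @export
setGeneric("relationMatrix", function(object) standardGeneric("relationMatrix"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname accessors
setMethod("counts", "CountTable", function(object) object@counts)
#' @rdname accessors
setMethod("compositions", "CompositionTable", function(object) object@x)
#' @rdname accessors
setMethod("relationMatrix", "SampleGraph", function(object) object@r)
#' @rdname accessors
setMethod("sampleIds", "CountTable", function(object) rownames(object@counts))
#' @rdname accessors
setMethod("sampleIds", "CompositionTable", function(object) rownames(object@x))
#' @rdname accessors
setMethod("sampleIds", "SampleGraph", function(object) rownames(object@r))
#' @rdname accessors
setMethod("featureIds", "CountTable", function(object) colnames(object@counts))
#' @rdname accessors
setMethod("featureIds", "CompositionTable", function(object) colnames(object@x))

#' @describeIn SNLFit-class per-sample coefficient matrix (the sparse b copies)
#' @param object an `SNLFit` object.
#' @export
setMethod("coef", "SNLFit", function(object) object@coefficients)

#' @describeIn LassoFit-class the shared zero-sum coefficient vector
#' @param object a `LassoFit` object.
#' @export
setMethod("coef", "LassoFit", function(object) object@coefficients)

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable: %d samples x %d features, total count %s\n",
              nrow(object@counts), ncol(object@counts),
              format(sum(object@counts))))
})

setMethod("show", "CompositionTable", function(object) {
  cat(sprintf("CompositionTable: %d samples x %d features on the simplex\n",
              nrow(object@x), ncol(object@x)))
})

setMethod("show", "SampleGraph", function(object) {
  r <- object@r
  cat(sprintf("SampleGraph: %d samples, %d weighted pairs\n",
              nrow(r), sum(r[upper.tri(r)] > 0)))
})

setMethod("show", "SNLFit", function(object) {
  cat(sprintf(
    "SNLFit (%s): %d samples x %d features\n  lambda1 = %g, lambda2 = %g; %d iterations (%s)\n  objective = %g; max residual = %g\n",
    if (object@constrained) "zero-sum constrained" else "unconstrained",
    nrow(object@coefficients), ncol(object@coefficients),
    object@lambda1, object@lambda2, object@iterations,
    if (object@converged) "converged" else "NOT converged",
    object@objective, max(object@residuals)))
})

setMethod("show", "LassoFit", function(object) {
  cat(sprintf(
    "LassoFit: p = %d, lambda = %g, %d nonzero, %d iterations (%s)\n",
    length(object@coefficients), object@lambda,
    sum(object@coefficients != 0), object@iterations,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "SimulationData", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SimulationData: n = %d (3 clusters), p = %d, sigma = %g, PR = %g, seed = %s\n  train/validation: %d/%d\n",
    length(object@y), ncol(object@z), cfg$sigma, cfg$pr,
    format(cfg$seed), length(object@trainIdx), length(object@validationIdx)))
})

setMethod("show", "CVResult", function(object) {
  b <- object@best
  cat(sprintf("CVResult: %d grid points, %d folds\n  selected: %s (mean CV error %g)\n",
              nrow(object@grid), object@K,
              paste(sprintf("%s = %g", names(object@grid), unlist(object@grid[b, ])),
                    collapse = ", "),
              object@meanError[b]))
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf("ClusterReport: %d samples in %d clusters (sizes %s)\n",
              length(object@labels), object@nClusters,
              paste(tabulate(object@labels, object@nClusters), collapse = ", ")))
})
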