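#' Solve the (constrained) Weber problem
#'
#' Finds the weighted geometric median of the anchor vectors:
#' `min_w sum_i r_i ||w - anchor_i||_2`, optionally subject to the zero-sum
#' constraint `sum_j w_j = 0`. This is how a coefficient vector is assigned
#' to a sample that was not in the training set: the anchors are the fitted
#' per-sample coefficient vectors and the weights are the new sample's graph
#' relations to the training samples. Solved by ADMM on the splitting
#' `e_i = w - anchor_i` (group soft-threshold e-updates).
#'
#' @param anchors n x p matrix of anchor vectors (fitted coefficients).
#' @param weights length-n nonnegative weights; at least one positive.
#'   Zero-weight anchors are dropped (they do not enter the objective).
#' @param constrained enforce the zero-sum constraint on the solution.
#' @param mu,eta positive ADMM tuning parameters (default one).
#' @param tol convergence tolerance (max primal residual, infinity norm).
#' @param maxIter iteration cap.
#' @return The length-p minimizer.
#' @export
solveWeber <- function(anchors, weights, constrained = TRUE,
                       mu = 1, eta = 1, tol = 1e-6, maxIter = 2000) {
  anchors <- as.matrix(anchors)
  stopifnot(length(weights) == nrow(anchors), all(weights >= 0))
  keep <- weights > 0
  if (!any(keep)) stop("all Weber weights are zero")
  anchors <- anchors[keep, , drop = FALSE]
  weights <- weights[keep]
  if (nrow(anchors) == 1 || all(sweep(anchors, 2, anchors[1, ]) == 0)) {
    w <- anchors[1, ]
    if (constrained && abs(sum(w)) > tol)
      w <- w - sum(w) / length(w)
    return(stats::setNames(w, colnames(anchors)))
  }
  res <- .admmWeber(anchors, weights, constrained, mu, eta, tol, maxIter)
  stats::setNames(drop(res$w), colnames(anchors))
}

#' Predict coefficient vectors and responses for new samples
#'
#' For each new sample, its coefficient vector is the solution of the
#' constrained (or unconstrained, matching the fit) Weber problem anchored
#' at the fitted per-sample coefficients with the new sample's graph weights
#' to the training samples; the prediction is `z_new' w* + offset` with the
#' training response mean as offset. A new sample whose weight row is all
#' zero has no graph neighbours; uniform weights are substituted with a
#' warning.
#'
#' @param fit an [SNLFit-class].
#' @param zNew m x p matrix of log-features for the new samples.
#' @param weightsNew m x n matrix of graph weights from each new sample to
#'   the n training samples (a single vector is taken as one sample).
#' @param ... passed to [solveWeber()] (`mu`, `eta`, `tol`, `maxIter`).
#' @return `predictCoefficients`: an m x p matrix of coefficient vectors.
#'   `predictResponse`: a length-m numeric vector of predicted responses.
#' @export
predictCoefficients <- function(fit, weightsNew, ...) {
  anchors <- coef(fit)
  if (is.null(dim(weightsNew))) weightsNew <- matrix(weightsNew, nrow = 1)
  stopifnot(ncol(weightsNew) == nrow(anchors))
  out <- matrix(NA_real_, nrow(weightsNew), ncol(anchors),
                dimnames = list(rownames(weightsNew), colnames(anchors)))
  for (i in seq_len(nrow(weightsNew))) {
    wts <- weightsNew[i, ]
    if (all(wts == 0)) {
      warning("new sample ", i, " has no graph neighbours; using uniform weights")
      wts <- rep(1, length(wts))
    }
    out[i, ] <- solveWeber(anchors, wts, constrained = fit@constrained, ...)
  }
  out
}

#' @rdname predictCoefficients
#' @export
predictResponse <- function(fit, zNew, weightsNew, ...) {
  zNew <- as.matrix(zNew)
  if (length(fit@zScale))
    zNew <- sweep(zNew, 2, fit@zScale, "/")
  if (is.null(dim(weightsNew))) weightsNew <- matrix(weightsNew, nrow = 1)
  wstar <- predictCoefficients(fit, weightsNew, ...)
  drop(rowSums(zNew * wstar)) + fit@yOffset
}

#' @describeIn predictCoefficients `predict` method for `SNLFit`; requires
#'   `zNew` and `weightsNew`.
#' @param object an [SNLFit-class].
#' @export
setMethod("predict", "SNLFit", function(object, zNew, weightsNew, ...) {
  predictResponse(object, zNew, weightsNew, ...)
})

#' @describeIn predictCoefficients `predict` method for the compositional
#'   lasso baseline: `z_new' beta + offset`.
#' @export
setMethod("predict", "LassoFit", function(object, zNew, ...) {
  zNew <- as.matrix(zNew)
  drop(zNew %*% object@coefficients) + object@yOffset
})
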