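#' Control parameters for the ADMM solvers
#'
#' @param rho,phi,psi positive ADMM tuning parameters for the fusion,
#'   sparsity and zero-sum blocks (all one by default).
#' @param tol convergence tolerance on the maximum primal residual
#'   (infinity norms of `w - a` and `w - b`, and `|1'w|`, `|1'b|` for a
#'   constrained fit).
#' @param maxIter iteration cap.
#' @param exactSolve use a dense linear solve in the w-update instead of the
#'   rank-structured Sherman-Morrison shortcut (slower; for verification).
#' @return A list of class `snlControl`.
#' @export
snlControl <- function(rho = 1, phi = 1, psi = 1, tol = 1e-4,
                       maxIter = 5000, exactSolve = FALSE) {
  stopifnot(rho > 0, phi > 0, psi > 0, tol > 0, maxIter >= 1)
  structure(list(rho = rho, phi = phi, psi = psi, tol = tol,
                 maxIter = as.integer(maxIter), exactSolve = exactSolve),
            class = "snlControl")
}

#' Soft-thresholding operator
#'
#' `S(x, kappa) = sign(x) * max(|x| - kappa, 0)`, the proximal operator of
#' `kappa * |x|`; odd in `x` and non-expansive.
#'
#' @param x numeric (vectorized).
#' @param kappa nonnegative threshold.
#' @return Thresholded values.
#' @export
softThreshold <- function(x, kappa) {
  stopifnot(all(kappa >= 0))
  sign(x) * pmax(abs(x) - kappa, 0)
}

#' Fused-pair proximal update
#'
#' Minimizer of
#' `lambda1 * r * ||a_ml - a_lm||_2 + (rho/2) (||u - a_ml||^2 + ||v - a_lm||^2)`
#' where `u = wm + sml` and `v = wl + slm`: the pair is pulled together by a
#' factor `theta = max(1 - lambda1 * r / (rho * ||u - v||), 0.5)`, clamped so
#' that `theta = 0.5` gives exact fusion `a_ml = a_lm = (u + v)/2`. The
#' update conserves the pair sum: `a_ml + a_lm = u + v`.
#'
#' @param wm,wl current coefficient vectors of the two samples.
#' @param sml,slm the corresponding scaled dual vectors.
#' @param lambda1 fusion penalty weight; @param r edge relation weight;
#' @param rho ADMM tuning parameter.
#' @return List with elements `aml`, `alm` and `theta`.
#' @export
fusionPairUpdate <- function(wm, wl, sml, slm, lambda1, r, rho = 1) {
  u <- wm + sml
  v <- wl + slm
  nrm <- sqrt(sum((u - v)^2))
  theta <- if (nrm > 0) max(1 - lambda1 * r / (rho * nrm), 0.5) else 0.5
  list(aml = theta * u + (1 - theta) * v,
       alm = (1 - theta) * u + theta * v,
       theta = theta)
}

# positive-weight edge list (m > l) of a relation matrix
.edgeList <- function(r) {
  idx <- which(lower.tri(r) & r > 0, arr.ind = TRUE)  # row > col
  if (!nrow(idx))
    return(list(edges = matrix(integer(), 0, 2), w = numeric()))
  list(edges = cbind(idx[, 1], idx[, 2]), w = r[idx])
}

#' Fit the sparse network lasso for compositional covariates
#'
#' Estimates one coefficient vector per sample in the locally symmetric
#' log-contrast model `y_i = z_i' w_i + e_i` by minimizing
#' \deqn{\sum_i (y_i - z_i'w_i)^2 + \lambda_1 \sum_{m>l} r_{m,l} \|w_m - w_l\|_2
#'   + \lambda_2 \sum_i \|w_i\|_1}
#' subject to `sum_j w_ij = 0` for every i when `constrained = TRUE`. The
#' group-lasso fusion term collapses coefficient vectors of related samples
#' into latent clusters; the l1 term selects features. Solved by ADMM with
#' closed-form updates; by default the response is centered internally and
#' the offset stored for prediction (see `center`).
#'
#' @param z n x p matrix of log-transformed compositions (see
#'   [logFeatures()]), or any covariate matrix for the unconstrained
#'   variant.
#' @param y length-n numeric response.
#' @param graph a [SampleGraph-class] or symmetric nonnegative matrix of
#'   relation weights.
#' @param lambda1 nonnegative fusion (network lasso) penalty.
#' @param lambda2 nonnegative l1 penalty.
#' @param constrained enforce the zero-sum (log-contrast) constraint.
#' @param center center the response by its mean before fitting and store
#'   the offset for prediction. A constant cannot be represented by
#'   zero-sum coefficients acting on log-features, so set this to `FALSE`
#'   when the response is already centered or the generating model has no
#'   intercept.
#' @param standardize scale the covariate columns to unit SD before
#'   fitting (storing the scale for prediction); only available for the
#'   unconstrained variant, since rescaling log-features destroys the
#'   log-contrast meaning of the zero-sum constraint. Columns are not
#'   mean-centered: the response offset (`center`) handles the intercept,
#'   and removing the columns' locations would discard between-sample
#'   level information that per-sample models use. Coefficients are
#'   reported on the scaled covariates.
#' @param control an [snlControl()] list.
#' @param init optional warm-start state (the `state` attribute of a
#'   previous fit on the same problem dimensions).
#' @return An [SNLFit-class]; the full ADMM state for warm starts is
#'   attached as `attr(fit, "state")`.
#' @seealso [predictResponse()], [cvSparseNetwork()], [objectiveValue()]
#' @export
fitSparseNetwork <- function(z, y, graph, lambda1, lambda2,
                             constrained = TRUE, center = TRUE,
                             standardize = FALSE,
                             control = snlControl(), init = NULL) {
  z <- as.matrix(z)
  n <- nrow(z)
  stopifnot(length(y) == n, lambda1 >= 0, lambda2 >= 0)
  if (standardize && constrained)
    stop("standardize is only available for the unconstrained variant")
  zScale <- numeric(0)
  if (standardize) {
    zScale <- apply(z, 2, stats::sd)
    if (any(zScale == 0)) stop("cannot standardize a constant covariate")
    z <- sweep(z, 2, zScale, "/")
  }
  r <- .graphMat(graph)
  if (nrow(r) != n) stop("graph dimension does not match the sample count")
  el <- .edgeList(r)
  offset <- if (center) mean(y) else 0
  yc <- y - offset
  res <- .admmSNL(z, yc, el$edges, el$w, lambda1, lambda2,
                  control$rho, control$phi, control$psi,
                  constrained, control$tol, control$maxIter,
                  control$exactSolve, init)
  B <- res$B
  dimnames(B) <- dimnames(z)
  W <- res$W
  dimnames(W) <- dimnames(z)
  fit <- new("SNLFit", coefficients = B, w = W, yOffset = offset,
             zScale = zScale,
             lambda1 = lambda1, lambda2 = lambda2, constrained = constrained,
             iterations = as.integer(res$iterations),
             converged = res$converged, residuals = res$residuals,
             objective = objectiveValue(z, yc, B, r, lambda1, lambda2))
  attr(fit, "state") <- res$state
  fit
}

#' Penalized objective of the sparse network lasso
#'
#' Evaluates
#' `sum_i (y_i - z_i'w_i)^2 + lambda1 * sum_{m>l} r_ml ||w_m - w_l||_2 +
#' lambda2 * sum_i ||w_i||_1` at a given coefficient matrix. `y` is used as
#' passed (center it first to match a fit's internal objective).
#'
#' @param z n x p covariate matrix; @param y length-n response;
#' @param w n x p coefficient matrix; @param graph relation weights;
#' @param lambda1,lambda2 penalty parameters.
#' @return The objective value (a scalar).
#' @export
objectiveValue <- function(z, y, w, graph, lambda1, lambda2) {
  r <- .graphMat(graph)
  rss <- sum((y - rowSums(z * w))^2)
  el <- .edgeList(r)
  fus <- 0
  if (nrow(el$edges))
    fus <- sum(el$w * sqrt(rowSums(
      (w[el$edges[, 1], , drop = FALSE] - w[el$edges[, 2], , drop = FALSE])^2)))
  rss + lambda1 * fus + lambda2 * sum(abs(w))
}

#' Fit the compositional lasso baseline
#'
#' A single zero-sum coefficient vector for all samples:
#' `min_beta sum_i (y_i - z_i'beta)^2 + lambda ||beta||_1` subject to
#' `sum_j beta_j = 0`. Solved by ADMM (splitting `beta = b` with
#' soft-thresholding; the zero-sum constraint handled by a scalar
#' multiplier). The returned coefficients are the sparse `b` copy.
#'
#' @param z n x p log-feature matrix; @param y length-n response;
#' @param lambda nonnegative l1 penalty.
#' @param center center the response by its mean (see [fitSparseNetwork()]).
#' @param control an [snlControl()] list (`rho` is unused here).
#' @return A [LassoFit-class].
#' @export
fitCompositionalLasso <- function(z, y, lambda, center = TRUE,
                                  control = snlControl()) {
  z <- as.matrix(z)
  n <- nrow(z); p <- ncol(z)
  stopifnot(length(y) == n, lambda >= 0)
  offset <- if (center) mean(y) else 0
  yc <- y - offset
  phi <- control$phi; psi <- control$psi
  M <- 2 * crossprod(z) + diag(phi, p) + matrix(psi, p, p)
  Mc <- chol(M)
  zty2 <- 2 * crossprod(z, yc)
  beta <- numeric(p); b <- numeric(p); tt <- numeric(p); u <- 0
  converged <- FALSE
  it <- 0L
  for (it in seq_len(control$maxIter)) {
    beta <- backsolve(Mc, backsolve(Mc, zty2 + phi * b - tt - u,
                                    transpose = TRUE))
    beta <- drop(beta)
    b <- softThreshold(beta + tt / phi, lambda / phi)
    tt <- tt + phi * (beta - b)
    u <- u + psi * sum(beta)
    resid <- max(max(abs(beta - b)), abs(sum(beta)), abs(sum(b)))
    if (!all(is.finite(beta))) stop("compositional lasso ADMM diverged")
    if (resid < control$tol) { converged <- TRUE; break }
  }
  names(b) <- colnames(z)
  new("LassoFit", coefficients = b, yOffset = offset, lambda = lambda,
      iterations = as.integer(it), converged = converged)
}
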