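#' Mean squared error
#'
#' @param y observed values; @param yhat predictions of the same length.
#' @return `mean((y - yhat)^2)`.
#' @export
mse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) > 0)
  mean((y - yhat)^2)
}

.makeFolds <- function(n, K, seed = NULL) {
  stopifnot(K >= 2, K <= n)
  if (!is.null(seed)) set.seed(seed)
  sample(rep(seq_len(K), length.out = n))
}

.defaultLambda1Grid <- 10^(-2:2)
.defaultLambda2Grid <- 10^(-3:1)

#' K-fold cross-validation for the sparse network lasso
#'
#' Random K-fold partition (seeded); for every `(lambda1, lambda2)` grid
#' point each fold is fitted on the remaining samples restricted to the
#' training subgraph of the relation matrix, held-out samples are predicted
#' through the Weber problem using their observed graph weights to the
#' fold's training samples, and the held-out MSE is recorded. The selected
#' point minimizes the mean CV error; exact ties are broken toward stronger
#' regularization (the later point in the lambda1-then-lambda2 ascending
#' grid order). Fits are warm-started along the grid within each fold.
#'
#' @param z n x p log-feature matrix; @param y length-n response;
#' @param graph relation weights ([SampleGraph-class] or matrix).
#' @param lambda1Grid,lambda2Grid candidate penalty values.
#' @param K number of folds (default 5); @param seed fold-assignment seed.
#' @param constrained zero-sum constraint flag, passed to the fits.
#' @param center,standardize response-centering and covariate
#'   standardization flags, passed to the fits (see [fitSparseNetwork()];
#'   standardization is recomputed inside each training fold).
#' @param control an [snlControl()] list used for the CV fits.
#' @param weberTol,weberMaxIter Weber solver settings for held-out
#'   prediction.
#' @return A [CVResult-class].
#' @export
cvSparseNetwork <- function(z, y, graph, lambda1Grid = .defaultLambda1Grid,
                            lambda2Grid = .defaultLambda2Grid, K = 5,
                            seed = NULL, constrained = TRUE, center = TRUE,
                            standardize = FALSE, control = snlControl(),
                            weberTol = 1e-5, weberMaxIter = 1000) {
  z <- as.matrix(z)
  n <- nrow(z)
  r <- .graphMat(graph)
  grid <- expand.grid(lambda2 = sort(lambda2Grid), lambda1 = sort(lambda1Grid))
  grid <- grid[order(grid$lambda1, grid$lambda2), c("lambda1", "lambda2")]
  rownames(grid) <- NULL
  folds <- .makeFolds(n, K, seed)
  errs <- matrix(NA_real_, nrow(grid), K)
  for (k in seq_len(K)) {
    tr <- which(folds != k)
    te <- which(folds == k)
    ztr <- z[tr, , drop = FALSE]
    rtr <- r[tr, tr, drop = FALSE]
    state <- NULL
    for (g in seq_len(nrow(grid))) {
      fit <- fitSparseNetwork(ztr, y[tr], rtr, grid$lambda1[g],
                              grid$lambda2[g], constrained = constrained,
                              center = center, standardize = standardize,
                              control = control, init = state)
      state <- attr(fit, "state")
      yhat <- predictResponse(fit, z[te, , drop = FALSE],
                              r[te, tr, drop = FALSE],
                              tol = weberTol, maxIter = weberMaxIter)
      errs[g, k] <- mse(y[te], yhat)
    }
  }
  meanErr <- rowMeans(errs)
  best <- max(which(meanErr == min(meanErr)))
  new("CVResult", grid = grid, meanError = meanErr,
      sdError = apply(errs, 1, stats::sd), foldErrors = errs,
      best = as.integer(best), K = as.integer(K),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' K-fold cross-validation for the compositional lasso
#'
#' Same protocol as [cvSparseNetwork()] but with the single shared
#' coefficient vector of [fitCompositionalLasso()]; held-out samples are
#' predicted directly (no Weber step needed).
#'
#' @inheritParams cvSparseNetwork
#' @param lambdaGrid candidate l1 penalty values.
#' @return A [CVResult-class] (the grid has one `lambda` column).
#' @export
cvCompositionalLasso <- function(z, y, lambdaGrid = 10^(-3:2), K = 5,
                                 seed = NULL, center = TRUE,
                                 control = snlControl()) {
  z <- as.matrix(z)
  n <- nrow(z)
  grid <- data.frame(lambda = sort(lambdaGrid))
  folds <- .makeFolds(n, K, seed)
  errs <- matrix(NA_real_, nrow(grid), K)
  for (k in seq_len(K)) {
    tr <- which(folds != k)
    te <- which(folds == k)
    for (g in seq_len(nrow(grid))) {
      fit <- fitCompositionalLasso(z[tr, , drop = FALSE], y[tr],
                                   grid$lambda[g], center = center,
                                   control = control)
      errs[g, k] <- mse(y[te], predict(fit, z[te, , drop = FALSE]))
    }
  }
  meanErr <- rowMeans(errs)
  best <- max(which(meanErr == min(meanErr)))
  new("CVResult", grid = grid, meanError = meanErr,
      sdError = apply(errs, 1, stats::sd), foldErrors = errs,
      best = as.integer(best), K = as.integer(K),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Selected regularization parameters of a CV run
#'
#' @param cv a [CVResult-class].
#' @return Named list of the selected grid row.
#' @export
selectedLambda <- function(cv) {
  as.list(cv@grid[cv@best, , drop = FALSE])
}

#' Leave-one-out cross-validated R-squared
#'
#' For each sample i the model is fitted on the other n - 1 samples and
#' sample i is predicted (through the Weber problem for the network model,
#' directly for the compositional lasso);
#' `R^2 = 1 - sum (y_i - yhat_i)^2 / sum (y_i - ybar)^2`. Always at most 1.
#'
#' @param z,y,graph data as in [cvSparseNetwork()] (`graph` ignored for
#'   `method = "lasso"`).
#' @param lambda1,lambda2 penalties for `method = "network"`; `lambda1` is
#'   the single l1 penalty for `method = "lasso"`.
#' @param method `"network"` (per-sample coefficients) or `"lasso"`.
#' @param constrained zero-sum flag for the network model.
#' @param center response-centering flag (see [fitSparseNetwork()]).
#' @param control an [snlControl()] list.
#' @return The LOOCV coefficient of determination.
#' @export
loocvR2 <- function(z, y, graph = NULL, lambda1, lambda2 = NULL,
                    method = c("network", "lasso"), constrained = TRUE,
                    center = TRUE, control = snlControl()) {
  method <- match.arg(method)
  z <- as.matrix(z)
  n <- nrow(z)
  stopifnot(n >= 3)
  if (stats::sd(y) == 0) stop("constant response: R^2 undefined")
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (method == "network") {
      r <- .graphMat(graph)
      fit <- fitSparseNetwork(z[tr, , drop = FALSE], y[tr],
                              r[tr, tr, drop = FALSE], lambda1, lambda2,
                              constrained = constrained, center = center,
                              control = control)
      yhat[i] <- predictResponse(fit, z[i, , drop = FALSE],
                                 r[i, tr, drop = FALSE])
    } else {
      fit <- fitCompositionalLasso(z[tr, , drop = FALSE], y[tr], lambda1,
                                   center = center, control = control)
      yhat[i] <- predict(fit, z[i, , drop = FALSE])
    }
  }
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}
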