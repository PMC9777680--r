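#' Run the simulation study
#'
#' For each design cell `(p, sigma, pr)` and repetition: simulate a dataset
#' ([simulateDataset()], seeded as `baseSeed + repetition`), select the
#' regularization parameters by K-fold CV on the training samples (with the
#' observed-graph training subgraph), fit on the training samples, predict
#' the validation samples (through the constrained / unconstrained Weber
#' problem for the network models, directly for the compositional lasso)
#' and record the validation MSE. The generative model has no intercept, so
#' the constrained model and the compositional lasso run with
#' `center = FALSE` on raw log-features; the unconstrained variant runs on
#' standardized covariates with a centered response, the generic
#' network-lasso model's stated assumptions. Reports mean and SD per method
#' and cell.
#'
#' @param cells data.frame with columns `p`, `sigma`, `pr` (one row per
#'   design cell).
#' @param methods subset of `"proposed"` (zero-sum constrained sparse
#'   network lasso), `"snl"` (unconstrained variant) and `"cl"`
#'   (compositional lasso baseline).
#' @param repetitions number of simulated datasets per cell.
#' @param lambda1Grid,lambda2Grid CV grids for the network models. The
#'   study default is a compact log-spaced grid (`{0.1, 1, 10, 100}` x
#'   `{0.01, 0.1, 1}`) that keeps the multi-cell protocol tractable on a
#'   single CPU.
#' @param lambdaGrid CV grid for the compositional lasso.
#' @param K folds; @param baseSeed integer base seed (repetition r uses
#'   `baseSeed + r`).
#' @param control [snlControl()] used for CV fits; `finalControl` for the
#'   final training fit of each repetition.
#' @param outDir optional directory; when given, per-repetition results and
#'   a manifest (config + seeds) are written there.
#' @param verbose print one line per repetition.
#' @return data.frame with one row per method x cell: `method`, `p`,
#'   `sigma`, `pr`, `meanMSE`, `sdMSE`, `reps`, `nonconverged`.
#' @export
runSimulationStudy <- function(cells,
                               methods = c("proposed", "snl", "cl"),
                               repetitions = 20,
                               lambda1Grid = c(0.1, 1, 10, 100),
                               lambda2Grid = c(0.01, 0.1, 1),
                               lambdaGrid = 10^(-3:2),
                               K = 5, baseSeed = 1,
                               control = snlControl(tol = 1e-4, maxIter = 250),
                               finalControl = snlControl(tol = 1e-4, maxIter = 3000),
                               outDir = NULL, verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  cells <- as.data.frame(cells)
  stopifnot(all(c("p", "sigma", "pr") %in% names(cells)), repetitions >= 1)
  perRep <- list()
  for (ci in seq_len(nrow(cells))) {
    p <- cells$p[ci]; sigma <- cells$sigma[ci]; pr <- cells$pr[ci]
    for (rep_ in seq_len(repetitions)) {
      sd_ <- baseSeed + rep_
      sim <- simulateDataset(p = p, sigma = sigma, pr = pr, seed = sd_)
      res <- .evaluateMethods(sim, methods, lambda1Grid, lambda2Grid,
                              lambdaGrid, K, cvSeed = sd_,
                              control = control, finalControl = finalControl)
      res$p <- p; res$sigma <- sigma; res$pr <- pr; res$rep <- rep_
      res$seed <- sd_
      perRep[[length(perRep) + 1]] <- res
      if (verbose)
        message(sprintf("cell (p=%d, sigma=%g, PR=%g) rep %d: %s",
                        p, sigma, pr, rep_,
                        paste(sprintf("%s=%.3f", res$method, res$mse),
                              collapse = " ")))
    }
  }
  long <- do.call(rbind, perRep)
  agg <- do.call(rbind, lapply(split(long, long[c("method", "p", "sigma", "pr")],
                                     drop = TRUE), function(d)
    data.frame(method = d$method[1], p = d$p[1], sigma = d$sigma[1],
               pr = d$pr[1], meanMSE = mean(d$mse), sdMSE = stats::sd(d$mse),
               reps = nrow(d), nonconverged = sum(!d$converged))))
  rownames(agg) <- NULL
  agg <- agg[order(agg$method, agg$p, agg$sigma, agg$pr), ]
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(long, file.path(outDir, "repetitions.csv"),
                     row.names = FALSE)
    utils::write.csv(agg, file.path(outDir, "summary.csv"), row.names = FALSE)
    manifest <- list(cells = cells, methods = methods,
                     repetitions = repetitions, K = K, baseSeed = baseSeed,
                     lambda1Grid = lambda1Grid, lambda2Grid = lambda2Grid,
                     lambdaGrid = lambdaGrid,
                     control = unclass(control),
                     finalControl = unclass(finalControl))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(agg, "repetitionsTable") <- long
  agg
}

# one simulated dataset -> per-method validation MSE
.evaluateMethods <- function(sim, methods, lambda1Grid, lambda2Grid,
                             lambdaGrid, K, cvSeed, control, finalControl) {
  tr <- sim@trainIdx; va <- sim@validationIdx
  ztr <- sim@z[tr, , drop = FALSE]; ytr <- sim@y[tr]
  r <- relationMatrix(sim@observedGraph)
  rtr <- r[tr, tr, drop = FALSE]
  out <- list()
  for (m in methods) {
    if (m == "cl") {
      cv <- cvCompositionalLasso(ztr, ytr, lambdaGrid, K = K, seed = cvSeed,
                                 center = FALSE, control = control)
      fit <- fitCompositionalLasso(ztr, ytr, selectedLambda(cv)$lambda,
                                   center = FALSE, control = finalControl)
      yhat <- predict(fit, sim@z[va, , drop = FALSE])
      conv <- fit@converged
    } else {
      # proposed: raw log-features, no intercept in the generative model.
      # snl: the generic model's stated assumptions -- standardized
      # covariates and a centered response.
      constrained <- (m == "proposed")
      std <- (m == "snl")
      cv <- cvSparseNetwork(ztr, ytr, rtr, lambda1Grid, lambda2Grid, K = K,
                            seed = cvSeed, constrained = constrained,
                            center = std, standardize = std,
                            control = control)
      sel <- selectedLambda(cv)
      fit <- fitSparseNetwork(ztr, ytr, rtr, sel$lambda1, sel$lambda2,
                              constrained = constrained, center = std,
                              standardize = std, control = finalControl)
      yhat <- predictResponse(fit, sim@z[va, , drop = FALSE],
                              r[va, tr, drop = FALSE])
      conv <- fit@converged
    }
    out[[m]] <- data.frame(method = m, mse = mse(sim@y[va], yhat),
                           converged = conv, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' End-to-end fitting pipeline on files
#'
#' Loads counts (or compositions) and a response, optionally aggregates
#' features on a phylogenetic tree, converts to compositions with zero
#' replacement, builds or loads the sample relation graph, selects
#' `(lambda1, lambda2)` by K-fold CV, fits the constrained (or
#' unconstrained) sparse network lasso, and writes the artifacts:
#' `coefficients.csv`, `cv_report.csv`, `clusters.csv`,
#' `coefficients_long.csv` and a `manifest.json` recording every parameter
#' and seed.
#'
#' @param countsPath CSV/TSV of counts (samples x features), or
#' @param compositionsPath CSV of closed compositions (one of the two).
#' @param responsePath CSV with columns `id`, `y` (or a single column of
#'   values in sample order).
#' @param graphPath optional dense-CSV relation graph; if absent the graph
#'   is built from `covariatesPath` (Gower distance) or from the
#'   compositions (log-ratio distance), per `distance`, with [knnRelationGraph()].
#' @param covariatesPath optional covariate CSV (first column sample id).
#' @param distance `"gower"` or `"logratio"`; @param k neighbours for the
#'   k-NN graph.
#' @param treePath optional Newick tree for [aggregateByCophenetic()];
#' @param aggThreshold its cophenetic cut (aggregation skipped when `NULL`).
#' @param zeroReplacement pseudo-count for [countsToComposition()].
#' @param lambda1Grid,lambda2Grid,K,seed CV settings.
#' @param constrained zero-sum constraint flag.
#' @param control an [snlControl()] list.
#' @param outDir output directory (created).
#' @return Invisibly, a list with the fit, CV result and cluster report.
#' @export
runFitPipeline <- function(countsPath = NULL, compositionsPath = NULL,
                           responsePath, graphPath = NULL,
                           covariatesPath = NULL,
                           distance = c("gower", "logratio"), k = 5,
                           treePath = NULL, aggThreshold = NULL,
                           zeroReplacement = 1,
                           lambda1Grid = .defaultLambda1Grid,
                           lambda2Grid = .defaultLambda2Grid,
                           K = 5, seed = 1, constrained = TRUE,
                           control = snlControl(), outDir) {
  distance <- match.arg(distance)
  if (is.null(countsPath) == is.null(compositionsPath))
    stop("provide exactly one of countsPath / compositionsPath")
  if (!is.null(countsPath)) {
    ct <- loadCounts(countsPath)
    if (!is.null(treePath) && !is.null(aggThreshold)) {
      tree <- ape::read.tree(treePath)
      ct <- aggregateByCophenetic(ct, tree, aggThreshold)
    }
    comp <- countsToComposition(ct, zeroReplacement)
  } else {
    df <- utils::read.csv(compositionsPath, row.names = 1, check.names = FALSE)
    comp <- CompositionTable(as.matrix(df))
  }
  ydf <- utils::read.csv(responsePath, check.names = FALSE)
  if (ncol(ydf) >= 2) {
    y <- ydf[[2]]
    names(y) <- as.character(ydf[[1]])
    y <- y[sampleIds(comp)]
    if (any(is.na(y))) stop("response file is missing samples: ",
                            paste(sampleIds(comp)[is.na(y)], collapse = ", "))
  } else {
    y <- ydf[[1]]
    if (length(y) != nrow(compositions(comp)))
      stop("response length does not match the sample count")
  }
  z <- logFeatures(comp)
  if (!is.null(graphPath)) {
    g <- readSampleGraph(graphPath)
  } else if (distance == "gower") {
    if (is.null(covariatesPath))
      stop("gower distance needs covariatesPath")
    cov <- utils::read.csv(covariatesPath, row.names = 1, check.names = FALSE,
                           stringsAsFactors = TRUE)
    cov <- cov[sampleIds(comp), , drop = FALSE]
    g <- knnRelationGraph(gowerDistances(cov), k = k)
  } else {
    g <- knnRelationGraph(logratioDistances(comp), k = k)
  }
  cv <- cvSparseNetwork(z, y, g, lambda1Grid, lambda2Grid, K = K, seed = seed,
                        constrained = constrained, control = control)
  sel <- selectedLambda(cv)
  fit <- fitSparseNetwork(z, y, g, sel$lambda1, sel$lambda2,
                          constrained = constrained, control = control)
  clusters <- extractFusedClusters(coef(fit))

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .writeIdMatrix(coef(fit), file.path(outDir, "coefficients.csv"))
  cvdf <- cbind(cv@grid, meanError = cv@meanError, sdError = cv@sdError,
                cv@foldErrors)
  names(cvdf)[-seq_len(ncol(cv@grid) + 2)] <- paste0("fold", seq_len(cv@K))
  utils::write.csv(cvdf, file.path(outDir, "cv_report.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample = rownames(coef(fit)),
                              cluster = clusters@labels),
                   file.path(outDir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(coefficientsLong(coef(fit)),
                   file.path(outDir, "coefficients_long.csv"),
                   row.names = FALSE)
  manifest <- list(countsPath = countsPath, compositionsPath = compositionsPath,
                   responsePath = responsePath, graphPath = graphPath,
                   covariatesPath = covariatesPath, distance = distance,
                   k = k, treePath = treePath, aggThreshold = aggThreshold,
                   zeroReplacement = zeroReplacement,
                   lambda1Grid = lambda1Grid, lambda2Grid = lambda2Grid,
                   K = K, seed = seed, constrained = constrained,
                   yOffset = fit@yOffset,
                   selected = sel, iterations = fit@iterations,
                   converged = fit@converged, objective = fit@objective,
                   control = unclass(control))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, cv = cv, clusters = clusters))
}
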