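#' True coefficient vectors of the three-cluster simulation design
#'
#' Three fixed zero-sum p-vectors: eight nonzero leading entries each,
#' padded with `p - 8` zeros. They define the three latent regression
#' clusters of the simulation study.
#'
#' @param p number of features, at least 8.
#' @return A 3 x p matrix whose rows each sum to zero.
#' @export
trueCoefficientMatrix <- function(p) {
  if (p < 8) stop("p must be at least 8")
  base <- rbind(
    c(1, -0.8, 0.6, 0,   0, -1.5, -0.5,  1.2),
    c(0, -0.5, 1,   1.2, 0.1, -1,  0,   -0.8),
    c(0,  0,   0,   0.8, 1,   0,  -0.8, -1))
  cbind(base, matrix(0, 3, p - 8))
}

# n x p draws from N(omega, Sigma): omega_j = log(0.5 p) for j <= 5 else 0,
# Sigma_ij = 0.2^|i-j| (AR(1)). Consumes the current RNG stream.
.latentGaussian <- function(n, p) {
  omega <- c(rep(log(0.5 * p), 5), rep(0, p - 5))
  Sigma <- 0.2^abs(outer(seq_len(p), seq_len(p), "-"))
  MASS::mvrnorm(n, omega, Sigma)
}

#' Generate logistic-normal compositions
#'
#' Latent vectors `c_i ~ N(omega, Sigma)` with `omega_j = log(0.5 p)` for
#' the first five coordinates (making those components dominant) and zero
#' otherwise, and AR(1) covariance `Sigma_ij = 0.2^|i - j|`, are mapped to
#' the simplex by the softmax closure `x_ij = exp(c_ij) / sum_k exp(c_ik)`.
#'
#' @param p number of features (at least 6); @param n number of samples.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param latent also return the pre-closure latent matrix.
#' @return A [CompositionTable-class], or (if `latent`) a list with
#'   elements `composition` and `latent`.
#' @export
generateCompositions <- function(p, n, seed = NULL, latent = FALSE) {
  stopifnot(p >= 6, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  C <- .latentGaussian(n, p)
  x <- exp(C) / rowSums(exp(C))
  dimnames(x) <- list(paste0("sample_", seq_len(n)),
                      paste0("taxon_", seq_len(p)))
  ct <- CompositionTable(x)
  if (latent) list(composition = ct, latent = C) else ct
}

#' Simulate one dataset from the three-cluster design
#'
#' Generates `n` samples in three equal clusters: logistic-normal
#' compositions, responses `y_i = z_i' w*(g_i) + sigma * e_i` with the
#' cluster-specific true zero-sum coefficient vectors of
#' [trueCoefficientMatrix()] and standard normal `e_i`, the exact block
#' graph of the cluster labels, its elementwise corruption (each
#' upper-triangle entry observed correctly with probability `pr`), and a
#' random train/validation split.
#'
#' All randomness comes from one stream seeded once, with a fixed draw
#' order (latent compositions, unit noise, corruption uniforms, split), so
#' the same seed with a different `sigma` keeps the compositions and noise
#' directions identical, and a different `pr` keeps everything but the
#' corruption pattern identical.
#'
#' @param p number of features (>= 8); @param sigma noise SD;
#' @param pr graph fidelity in (0, 1]; @param n samples (multiple of 3);
#' @param nTrain training-set size; @param seed integer seed.
#' @return A [SimulationData-class].
#' @export
simulateDataset <- function(p = 30, sigma = 0.1, pr = 0.99, n = 120,
                            nTrain = 100, seed = 1) {
  stopifnot(p >= 8, sigma > 0, pr > 0, pr <= 1, n %% 3 == 0, nTrain < n)
  set.seed(seed)
  C <- .latentGaussian(n, p)
  e0 <- stats::rnorm(n)
  uCorr <- stats::runif(n * (n - 1) / 2)
  trainIdx <- sort(sample(n, nTrain))

  x <- exp(C) / rowSums(exp(C))
  dimnames(x) <- list(paste0("sample_", seq_len(n)),
                      paste0("taxon_", seq_len(p)))
  comp <- CompositionTable(x)
  z <- log(x)
  labels <- rep(1:3, each = n / 3)
  Wtrue <- trueCoefficientMatrix(p)[labels, , drop = FALSE]
  dimnames(Wtrue) <- dimnames(z)
  y <- rowSums(z * Wtrue) + sigma * e0
  trueG <- blockGraph(labels)
  obsG <- .applyCorruption(relationMatrix(trueG), pr, uCorr)
  new("SimulationData", composition = comp, z = z, y = y,
      clusters = as.integer(labels), trueCoefficients = Wtrue,
      trueGraph = trueG, observedGraph = obsG,
      trainIdx = trainIdx,
      validationIdx = setdiff(seq_len(n), trainIdx),
      config = list(p = p, sigma = sigma, pr = pr, n = n,
                    nTrain = nTrain, seed = seed))
}
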