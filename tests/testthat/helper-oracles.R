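# Independent oracles for the convex problems the ADMM solvers address.
# Both work on a smoothed objective (sqrt(x^2 + delta^2)) minimized by BFGS
# with delta-continuation, in null-space coordinates for the zero-sum
# constraint; the Weber oracle is IRLS (Weiszfeld-type). None of them share
# code or algorithm with the package's solvers.

# orthonormal basis of the zero-sum subspace of R^p
.nullBasis <- function(p) {
  qr.Q(qr(matrix(1, p, 1)), complete = TRUE)[, -1, drop = FALSE]
}

# minimize the sparse-network-lasso objective by smoothed BFGS;
# returns the true (unsmoothed) objective at the minimizer and the matrix
oracleNetworkMin <- function(z, y, r, lambda1, lambda2, constrained,
                             deltas = c(1e-2, 1e-4, 1e-6, 1e-8)) {
  n <- nrow(z); p <- ncol(z)
  el <- which(lower.tri(r) & r > 0, arr.ind = TRUE)
  ew <- r[el]
  N <- if (constrained) .nullBasis(p) else diag(p)
  q <- ncol(N)
  toW <- function(th) matrix(th, n, q) %*% t(N)
  objS <- function(th, delta) {
    W <- toW(th)
    rss <- sum((y - rowSums(z * W))^2)
    fus <- 0
    if (nrow(el))
      fus <- sum(ew * sqrt(rowSums((W[el[, 1], , drop = FALSE] -
                                      W[el[, 2], , drop = FALSE])^2) + delta^2))
    rss + lambda1 * fus + lambda2 * sum(sqrt(W^2 + delta^2))
  }
  gradS <- function(th, delta) {
    W <- toW(th)
    res <- y - rowSums(z * W)
    G <- -2 * res * z
    if (nrow(el)) {
      D <- W[el[, 1], , drop = FALSE] - W[el[, 2], , drop = FALSE]
      cf <- lambda1 * ew / sqrt(rowSums(D^2) + delta^2)
      for (e in seq_len(nrow(el))) {
        G[el[e, 1], ] <- G[el[e, 1], ] + cf[e] * D[e, ]
        G[el[e, 2], ] <- G[el[e, 2], ] - cf[e] * D[e, ]
      }
    }
    G <- G + lambda2 * W / sqrt(W^2 + delta^2)
    as.vector(G %*% N)
  }
  th <- numeric(n * q)
  for (delta in deltas) {
    op <- stats::optim(th, objS, gradS, delta = delta, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-14))
    th <- op$par
  }
  W <- toW(th)
  list(objective = compnetlasso::objectiveValue(z, y, W, r, lambda1, lambda2),
       w = W)
}

# weighted geometric median by IRLS, optionally on the zero-sum plane
oracleWeberMin <- function(anchors, wts, constrained,
                           maxIter = 10000, eps = 1e-12) {
  obj <- function(w) sum(wts * sqrt(rowSums(sweep(anchors, 2, w)^2)))
  w <- colSums(anchors * wts) / sum(wts)
  if (constrained) w <- w - mean(w)
  for (k in seq_len(maxIter)) {
    d <- sqrt(rowSums(sweep(anchors, 2, w)^2))
    q <- wts / pmax(d, eps)
    wNew <- colSums(anchors * q) / sum(q)
    if (constrained) wNew <- wNew - mean(wNew)
    if (max(abs(wNew - w)) < 1e-13) { w <- wNew; break }
    w <- wNew
  }
  list(w = w, objective = obj(w))
}

# equality-constrained least squares by its KKT system (for the lambda = 0
# compositional lasso): min ||y - Z b||^2 s.t. 1'b = 0
kktZeroSumLS <- function(z, y) {
  p <- ncol(z)
  K <- rbind(cbind(2 * crossprod(z), rep(1, p)), c(rep(1, p), 0))
  drop(solve(K, c(2 * crossprod(z, y), 0)))[seq_len(p)]
}

# small random problem generator used across solver tests
randomProblem <- function(n, p, density = 0.8, sigma = 0.5) {
  z <- matrix(stats::rnorm(n * p), n, p)
  y <- stats::rnorm(n, sd = 2)
  r <- matrix(stats::runif(n * n) < density, n, n) * 1
  r[lower.tri(r, diag = TRUE)] <- 0
  r <- r + t(r)
  list(z = z, y = y, r = r)
}
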