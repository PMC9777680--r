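test_that("soft threshold is the l1 prox: odd and non-expansive", {
  expect_equal(softThreshold(3, 1), 2)
  expect_equal(softThreshold(-0.5, 1), 0)
  expect_equal(softThreshold(-3, 1), -2)
  expect_equal(softThreshold(1.7, 0), 1.7)
  set.seed(11)
  x <- rnorm(200, sd = 3); k <- runif(200, 0, 2)
  expect_equal(softThreshold(-x, k), -softThreshold(x, k))
  expect_true(all(abs(softThreshold(x, k)) <= abs(x)))
})

test_that("fusion pair update clamps theta and conserves the pair sum", {
  p <- 4
  set.seed(12)
  for (rep in 1:1000) {
    wm <- rnorm(p); wl <- rnorm(p); sml <- rnorm(p, sd = .3); slm <- rnorm(p, sd = .3)
    l1 <- runif(1, 0, 5); r <- runif(1); rho <- runif(1, 0.5, 2)
    up <- fusionPairUpdate(wm, wl, sml, slm, l1, r, rho)
    expect_true(up$theta >= 0.5 && up$theta <= 1)
    expect_equal(up$aml + up$alm, (wm + sml) + (wl + slm), tolerance = 1e-12)
    if (up$theta == 0.5) expect_equal(up$aml, up$alm, tolerance = 1e-12)
  }
  # lambda1 = 0: identity; strong penalty: exact fusion at the midpoint
  u <- c(1, 2); v <- c(-1, 0)
  id <- fusionPairUpdate(u, v, c(0, 0), c(0, 0), 0, 1, 1)
  expect_equal(id$aml, u); expect_equal(id$alm, v); expect_equal(id$theta, 1)
  fu <- fusionPairUpdate(u, v, c(0, 0), c(0, 0), 100, 1, 1)
  expect_equal(fu$theta, 0.5)
  expect_equal(fu$aml, (u + v) / 2)
})

test_that("fusion pair update minimizes its proximal objective", {
  # compare with a smoothed numeric minimization over the 2p variables
  set.seed(13)
  p <- 3
  for (rep in 1:20) {
    wm <- rnorm(p); wl <- rnorm(p); sml <- rnorm(p, sd = .2); slm <- rnorm(p, sd = .2)
    l1 <- runif(1, 0.1, 2); r <- runif(1, 0.2, 1); rho <- 1
    u <- wm + sml; v <- wl + slm
    up <- fusionPairUpdate(wm, wl, sml, slm, l1, r, rho)
    proxObj <- function(a) {
      aml <- a[1:p]; alm <- a[(p + 1):(2 * p)]
      l1 * r * sqrt(sum((aml - alm)^2)) +
        rho / 2 * (sum((u - aml)^2) + sum((v - alm)^2))
    }
    op <- optim(c(u, v), function(a) {
      aml <- a[1:p]; alm <- a[(p + 1):(2 * p)]
      l1 * r * sqrt(sum((aml - alm)^2) + 1e-16) +
        rho / 2 * (sum((u - aml)^2) + sum((v - alm)^2))
    }, method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
    expect_lte(proxObj(c(up$aml, up$alm)), op$value + 1e-7)
  }
})

test_that("the rank-structured w-update solve matches a dense solve", {
  set.seed(14)
  p <- 5
  for (rep in 1:20) {
    z <- rnorm(p); cc <- runif(1, 0.5, 5); rhs <- rnorm(p)
    for (psi in c(0, 1, 2.5)) {
      A <- 2 * tcrossprod(z) + cc * diag(p) + psi * matrix(1, p, p)
      expect_equal(drop(compnetlasso:::.solveRankSystem(z, cc, psi, rhs)),
                   drop(solve(A, rhs)), tolerance = 1e-8)
    }
  }
  # zero covariate row degenerates to the ridge-only system
  expect_equal(drop(compnetlasso:::.solveRankSystem(rep(0, 3), 2, 0, c(2, 4, 6))),
               c(1, 2, 3))
})

test_that("objective value matches brute-force term-by-term summation", {
  set.seed(15)
  pb <- randomProblem(6, 4)
  w <- matrix(rnorm(24), 6, 4)
  brute <- 0
  for (i in 1:6) brute <- brute + (pb$y[i] - sum(pb$z[i, ] * w[i, ]))^2
  for (m in 2:6) for (l in 1:(m - 1))
    brute <- brute + 1.3 * pb$r[m, l] * sqrt(sum((w[m, ] - w[l, ])^2))
  brute <- brute + 0.7 * sum(abs(w))
  expect_equal(objectiveValue(pb$z, pb$y, w, pb$r, 1.3, 0.7), brute,
               tolerance = 1e-12)
  expect_equal(objectiveValue(pb$z, pb$y, 0 * w, pb$r, 1.3, 0.7),
               sum(pb$y^2), tolerance = 1e-12)
  expect_equal(objectiveValue(pb$z, pb$y, w, pb$r, 0, 0),
               sum((pb$y - rowSums(pb$z * w))^2), tolerance = 1e-12)
})

test_that("one ADMM iteration from zeros reproduces hand-computed updates", {
  # n = 2, p = 2, one edge of weight 1; all state starts at zero
  z <- matrix(c(1, 2,
                3, -1), 2, 2, byrow = TRUE)
  y <- c(1, -2)
  r <- matrix(c(0, 1, 1, 0), 2, 2)
  l1 <- 0.5; l2 <- 0.2
  fit <- fitSparseNetwork(z, y, r, l1, l2, constrained = TRUE, center = FALSE,
                          control = snlControl(maxIter = 1))
  # hand computation, scalar algebra (rho = phi = psi = 1, deg = 1):
  # w_i solves (2 z_i z_i' + 2 I + 11') w = 2 y_i z_i
  w1 <- solve(2 * tcrossprod(z[1, ]) + 2 * diag(2) + matrix(1, 2, 2),
              2 * y[1] * z[1, ])
  w2 <- solve(2 * tcrossprod(z[2, ]) + 2 * diag(2) + matrix(1, 2, 2),
              2 * y[2] * z[2, ])
  # fusion: theta = max(1 - l1 / ||w1... (edge (2,1): u = w2, v = w1)
  nrm <- sqrt(sum((w2 - w1)^2))
  th <- max(1 - l1 / nrm, 0.5)
  # b = S(w + t, l2) with t = 0
  b1 <- sign(w1) * pmax(abs(w1) - l2, 0)
  b2 <- sign(w2) * pmax(abs(w2) - l2, 0)
  expect_equal(fit@w, rbind(w1, w2), ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(coef(fit), rbind(b1, b2), ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(fit@iterations, 1L)
})

test_that("network lasso fits agree with an independent convex oracle", {
  set.seed(16)
  for (constrained in c(TRUE, FALSE)) {
    for (rep in 1:5) {
      n <- sample(3:4, 1); p <- sample(4:5, 1)
      pb <- randomProblem(n, p)
      l1 <- runif(1, 0.1, 1); l2 <- runif(1, 0.05, 0.5)
      fit <- fitSparseNetwork(pb$z, pb$y, pb$r, l1, l2,
                              constrained = constrained, center = FALSE,
                              control = snlControl(tol = 1e-7, maxIter = 20000))
      ours <- objectiveValue(pb$z, pb$y, coef(fit), pb$r, l1, l2)
      orc <- oracleNetworkMin(pb$z, pb$y, pb$r, l1, l2, constrained)
      expect_lte(abs(ours - orc$objective) / abs(orc$objective), 1e-3)
      if (constrained)
        expect_true(all(abs(rowSums(coef(fit))) <= 1e-4))
    }
  }
})

test_that("full shrinkage, fusion limit, and monotone l1 path hold", {
  set.seed(17)
  pb <- randomProblem(5, 4)
  # enormous l2 kills every coefficient
  big <- 10 * max(abs(2 * pb$y * pb$z))
  fit0 <- fitSparseNetwork(pb$z, pb$y, pb$r, 0.1, big, center = FALSE,
                           control = snlControl(tol = 1e-6, maxIter = 10000))
  expect_true(all(coef(fit0) == 0))
  # complete unit graph with large l1: all rows fuse, and the shared row
  # solves the pooled zero-sum lasso
  rfull <- 1 - diag(5)
  fitF <- fitSparseNetwork(pb$z, pb$y, rfull, 50, 0.1, center = FALSE,
                           control = snlControl(tol = 1e-7, maxIter = 20000))
  B <- coef(fitF)
  expect_lt(max(abs(sweep(B, 2, B[1, ]))), 1e-3)
  pooled <- fitCompositionalLasso(pb$z, pb$y, 5 * 0.1, center = FALSE,
                                  control = snlControl(tol = 1e-8, maxIter = 50000))
  expect_equal(B[1, ], coef(pooled), tolerance = 1e-2, ignore_attr = TRUE)
  # ||b||_1 never increases along an increasing l2 grid
  l1s <- vapply(c(0.01, 0.1, 0.5, 1, 5), function(l2)
    sum(abs(coef(fitSparseNetwork(pb$z, pb$y, pb$r, 0.2, l2, center = FALSE,
                                  control = snlControl(tol = 1e-6, maxIter = 20000))))),
    numeric(1))
  expect_true(all(diff(l1s) <= 1e-4))
})

test_that("compositional lasso matches KKT at lambda = 0 and the oracle", {
  set.seed(18)
  n <- 12; p <- 5
  z <- matrix(rnorm(n * p), n, p)
  beta0 <- c(1, -0.5, 0.25, -0.75, 0)
  y <- drop(z %*% beta0) + rnorm(n, sd = 0.1)
  fit <- fitCompositionalLasso(z, y, 0, center = FALSE,
                               control = snlControl(tol = 1e-9, maxIter = 100000))
  expect_equal(coef(fit), kktZeroSumLS(z, y), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lte(abs(sum(coef(fit))), 1e-4)
  # l1-penalized case against the smoothed convex oracle (an empty graph
  # with identical rows makes the pooled problem a single-sample network)
  lam <- 0.8
  fitL <- fitCompositionalLasso(z, y, lam, center = FALSE,
                                control = snlControl(tol = 1e-8, maxIter = 100000))
  objL <- function(b) sum((y - drop(z %*% b))^2) + lam * sum(abs(b))
  # smoothed-BFGS oracle in the zero-sum null space
  N <- qr.Q(qr(matrix(1, p, 1)), complete = TRUE)[, -1, drop = FALSE]
  th <- rep(0, p - 1)
  for (delta in c(1e-2, 1e-4, 1e-6, 1e-8)) {
    op <- optim(th, function(t_) {
      b <- drop(N %*% t_)
      sum((y - drop(z %*% b))^2) + lam * sum(sqrt(b^2 + delta^2))
    }, method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
    th <- op$par
  }
  bOrc <- drop(N %*% th)
  expect_lte(abs(objL(coef(fitL)) - objL(bOrc)) / objL(bOrc), 1e-3)
  # enormous lambda gives the zero vector
  fitB <- fitCompositionalLasso(z, y, 10 * max(abs(2 * crossprod(z, y))),
                                center = FALSE,
                                control = snlControl(tol = 1e-7, maxIter = 50000))
  expect_true(all(coef(fitB) == 0))
})

test_that("the exact dense w-update solve gives the same fit", {
  set.seed(19)
  pb <- randomProblem(6, 4)
  a <- fitSparseNetwork(pb$z, pb$y, pb$r, 0.5, 0.1, center = FALSE,
                        control = snlControl(tol = 1e-6, maxIter = 5000))
  b <- fitSparseNetwork(pb$z, pb$y, pb$r, 0.5, 0.1, center = FALSE,
                        control = snlControl(tol = 1e-6, maxIter = 5000,
                                             exactSolve = TRUE))
  expect_equal(coef(a), coef(b), tolerance = 1e-8)
})
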