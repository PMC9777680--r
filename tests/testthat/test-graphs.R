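test_that("Gower distances follow the mixed-variable formula", {
  cov <- data.frame(sex = c("F", "F", "M"), age = c(20, 40, 60))
  d <- gowerDistances(cov)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_equal(d, t(d))
  # sex equal, ages 20 vs 40, range 40: (0 + 20/40) / 2
  expect_equal(d[1, 2], 0.25)
  # sex differs, ages 20 vs 60: (1 + 40/40) / 2
  expect_equal(d[1, 3], 1)
  onecat <- data.frame(g = c("a", "b"))
  expect_equal(gowerDistances(onecat)[1, 2], 1)
  same <- data.frame(g = c("a", "a"), x = c(3, 3))
  expect_equal(gowerDistances(same)[1, 2], 0)
  # constant numeric column contributes zero, not NaN
  const <- data.frame(x = c(5, 5, 5), y = c(1, 2, 3))
  expect_true(all(is.finite(gowerDistances(const))))
  expect_error(gowerDistances(data.frame()), "at least one")
})

test_that("log-ratio distance is the Euclidean distance of clr rows", {
  x <- matrix(c(0.5, 0.3, 0.2,
                0.2, 0.5, 0.3), 2, 3, byrow = TRUE)
  ct <- CompositionTable(x)
  d <- logratioDistances(ct)
  clr1 <- log(x[1, ]) - mean(log(x[1, ]))
  clr2 <- log(x[2, ]) - mean(log(x[2, ]))
  expect_equal(d[1, 2], sqrt(sum((clr1 - clr2)^2)), tolerance = 1e-12)
  expect_equal(d[1, 1], 0)
  # metric property on random triples
  set.seed(3)
  xr <- compositions(countsToComposition(CountTable(matrix(rpois(120, 6), 12, 10))))
  dr <- logratioDistances(CompositionTable(xr))
  for (k in 1:20) {
    ijk <- sample(12, 3)
    expect_lte(dr[ijk[1], ijk[2]],
               dr[ijk[1], ijk[3]] + dr[ijk[3], ijk[2]] + 1e-12)
  }
})

test_that("k-NN relation graphs have half-weight one-directional edges", {
  d <- matrix(c(0, 1, 4,
                1, 0, 2,
                4, 2, 0), 3, 3)
  # 1-NN of each: 1 -> 2, 2 -> 1, 3 -> 2; so edge {1,2} mutual, {2,3} one-way
  r <- relationMatrix(knnRelationGraph(d, k = 1))
  expect_equal(r[1, 2], 1)
  expect_equal(r[2, 3], 0.5)
  expect_equal(r[1, 3], 0)
  set.seed(4)
  dm <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
  g <- knnRelationGraph(dm, k = 5)
  rm_ <- relationMatrix(g)
  expect_true(all(rm_ %in% c(0, 0.5, 1)))
  expect_equal(diag(rm_), rep(0, 20), ignore_attr = TRUE)
  expect_equal(rm_, t(rm_))
  # each sample contributes exactly k directed edges: total weight = n*k/2
  expect_equal(sum(rm_) / 2, 20 * 5 / 2)
  # distance ties broken toward the smaller index: everyone picks the
  # smallest available index, so 1 <-> 2 is mutual and 3, 4 point at 1
  dt <- matrix(1, 4, 4); diag(dt) <- 0
  rt <- relationMatrix(knnRelationGraph(dt, k = 1))
  expect_equal(rt[1, 2], 1)
  expect_equal(rt[1, 3], 0.5)
  expect_equal(rt[1, 4], 0.5)
  expect_equal(rt[2, 3], 0)
  # k = n - 1 gives the complete graph
  expect_true(all(relationMatrix(knnRelationGraph(d, k = 2)) ==
                    (1 - diag(3))))
  expect_error(knnRelationGraph(d, k = 3), "k must")
})

test_that("block graphs encode shared cluster labels", {
  expect_true(all(relationMatrix(blockGraph(c(1, 1, 1))) == 1 - diag(3)))
  expect_true(all(relationMatrix(blockGraph(1:3)) == 0))
  r <- relationMatrix(blockGraph(c(1, 1, 2)))
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], 0)
  expect_equal(r[2, 3], 0)
})

test_that("graph corruption flips entries at rate 1 - PR, symmetrically", {
  g <- blockGraph(rep(1:3, each = 40))
  expect_equal(relationMatrix(corruptGraph(g, pr = 1, seed = 1)),
               relationMatrix(g))
  pr <- 0.8
  gc <- corruptGraph(g, pr = pr, seed = 42)
  rc <- relationMatrix(gc)
  expect_equal(rc, t(rc))
  expect_equal(diag(rc), rep(0, 120), ignore_attr = TRUE)
  expect_true(all(rc %in% c(0, 1)))
  ut <- upper.tri(rc)
  agree <- mean(rc[ut] == relationMatrix(g)[ut])
  npair <- sum(ut)
  expect_lt(abs(agree - pr), 3 * sqrt(pr * (1 - pr) / npair))
  # seeded determinism, and different seeds give different corruptions
  expect_equal(relationMatrix(corruptGraph(g, pr, seed = 42)), rc)
  expect_false(identical(relationMatrix(corruptGraph(g, pr, seed = 43)), rc))
  expect_error(corruptGraph(g, pr = 0), "pr must")
})

test_that("sample graphs round-trip through dense and edge-list files", {
  r <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  r[1, 2] <- r[2, 1] <- 1
  r[3, 4] <- r[4, 3] <- 0.5
  g <- SampleGraph(r)
  dense <- file.path(tempdir(), "g.csv")
  writeSampleGraph(g, dense, "dense")
  expect_equal(relationMatrix(readSampleGraph(dense, "dense")), r)
  el <- file.path(tempdir(), "g.tsv")
  writeSampleGraph(g, el, "edgelist")
  back <- readSampleGraph(el, "edgelist", ids = paste0("s", 1:4))
  expect_equal(relationMatrix(back), r)
})
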