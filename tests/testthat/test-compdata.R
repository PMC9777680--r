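test_that("count tables round-trip through CSV and TSV unchanged", {
  m <- matrix(c(0, 3, 5, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("f1", "f2")))
  ct <- CountTable(m)
  for (ext in c("csv", "tsv")) {
    path <- file.path(tempdir(), paste0("counts.", ext))
    writeCounts(ct, path)
    back <- loadCounts(path)
    expect_identical(counts(back), m)
  }
})

test_that("invalid count tables are rejected", {
  expect_error(CountTable(matrix(c(1, -1, 2, 3), 2, 2)), "nonnegative")
  expect_error(CountTable(matrix(1:4, 2, 2,
                                 dimnames = list(c("a", "a"), c("x", "y")))),
               "duplicated")
  expect_error(loadCounts(file.path(tempdir(), "no_such_file.csv")),
               "not found")
  path <- file.path(tempdir(), "neg.csv")
  writeLines(c("id,f1,f2", "s1,1,-2", "s2,3,4"), path)
  expect_error(loadCounts(path), "nonnegative")
})

test_that("zero replacement and closure put rows on the simplex", {
  ct <- CountTable(matrix(c(0, 3, 2, 2), 2, 2, byrow = TRUE))
  x <- compositions(countsToComposition(ct, zeroReplacement = 1))
  expect_equal(x[1, ], c(feature_1 = 0.25, feature_2 = 0.75))
  expect_equal(x[2, ], c(feature_1 = 0.5, feature_2 = 0.5))
  set.seed(7)
  big <- CountTable(matrix(rpois(200, 3), 20, 10))
  xb <- compositions(countsToComposition(big))
  expect_true(all(abs(rowSums(xb) - 1) < 1e-10))
  expect_true(all(xb > 0))
  allz <- CountTable(matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE))
  expect_error(countsToComposition(allz, zeroReplacement = 0), "zero total")
})

test_that("log features are natural logs and invert exactly", {
  x <- matrix(c(1 / exp(1), 1 - 1 / exp(1)), 1, 2)
  z <- logFeatures(CompositionTable(x))
  expect_equal(z[1, 1], -1)
  p <- 5
  unif <- CompositionTable(matrix(1 / p, 3, p))
  expect_true(all(logFeatures(unif) == -log(p)))
  set.seed(1)
  xc <- compositions(countsToComposition(CountTable(matrix(rpois(60, 5), 6, 10))))
  expect_equal(exp(logFeatures(CompositionTable(xc))), xc, tolerance = 1e-12)
})

test_that("clr rows are centered and match the direct formula", {
  unif <- CompositionTable(matrix(0.25, 2, 4))
  expect_true(all(clrFeatures(unif) == 0))
  x <- matrix(c(0.5, 0.25, 0.25), 1, 3)
  got <- clrFeatures(CompositionTable(x))
  direct <- log(x) - mean(log(x))     # frozen formula evaluation
  expect_equal(as.vector(got), as.vector(direct), tolerance = 1e-12)
  set.seed(2)
  xc <- compositions(countsToComposition(CountTable(matrix(rpois(80, 4), 8, 10))))
  cc <- CompositionTable(xc)
  expect_true(all(abs(rowSums(clrFeatures(cc))) < 1e-10))
  # clr equals log-transform followed by row centering, exactly
  z <- logFeatures(cc)
  expect_identical(clrFeatures(cc), z - rowMeans(z))
})

test_that("cophenetic aggregation merges strictly below the threshold", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  # cophenetic distances: d(A,B) = 2, d(A,C) = d(B,C) = 3
  m <- matrix(c(1, 2, 3,
                4, 5, 6), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  ct <- CountTable(m)
  agg <- aggregateByCophenetic(ct, tree, threshold = 2.5)
  expect_identical(featureIds(agg), c("A", "C"))
  expect_equal(unname(counts(agg)[, "A"]), c(3, 9))   # A + B summed
  expect_equal(unname(counts(agg)[, "C"]), c(3, 6))
  # threshold 0: nothing merges; threshold above the diameter: all merge
  expect_identical(counts(aggregateByCophenetic(ct, tree, 0)), m)
  all1 <- aggregateByCophenetic(ct, tree, 10)
  expect_equal(unname(counts(all1)[, 1]), unname(rowSums(m)))
  expect_identical(featureIds(all1), "A")
  # exact threshold at a merge height is excluded (strict <)
  expect_identical(counts(aggregateByCophenetic(ct, tree, 2)), m)
  # mass conservation and idempotence
  expect_equal(sum(counts(agg)), sum(m))
  again <- aggregateByCophenetic(agg, tree, threshold = 2.5)
  expect_identical(counts(again), counts(agg))
  # features absent from the tree are an error
  bad <- CountTable(matrix(1:4, 2, 2,
                           dimnames = list(c("s1", "s2"), c("A", "Z"))))
  expect_error(aggregateByCophenetic(bad, tree, 1), "missing from tree")
})
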