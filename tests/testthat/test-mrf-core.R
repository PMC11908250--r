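test_that("node response standardization hits the 0-1 scale exactly", {
  z <- standardizeNodeResponses(cbind(c(1, 2, 3)))
  expect_equal(as.numeric(z), c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
  expect_false(attr(z, "inert"))

  z2 <- standardizeNodeResponses(cbind(c(5, 5, 5), c(1, 4, 7)))
  expect_equal(z2[, 1], c(0, 0, 0))
  expect_identical(attr(z2, "inert"), c(TRUE, FALSE))

  set.seed(8)
  z3 <- standardizeNodeResponses(matrix(rnorm(40), 10, 4))
  expect_lt(max(abs(colMeans(z3))), 1e-12)
  expect_lt(max(abs(colMeans(z3^2) - 1)), 1e-12)

  expect_error(standardizeNodeResponses(matrix(0, 0, 2)), "empty")
})

test_that("per-response split statistic matches hand computation", {
  expect_equal(splitStatistic(c(-1, -1, 1, 1), 1:2, 3:4), 4)
  expect_equal(splitStatistic(c(-1, 1, -1, 1), 1:2, 3:4), 0)
  expect_equal(splitStatistic(c(0, 0, 0, 0), 1:2, 3:4), 0) # inert column
  expect_error(splitStatistic(c(1, 2), integer(0), 1:2), "non-empty")
  expect_error(splitStatistic(c(1, 2, 3), 1:2, 2:3), "partition")
})

test_that("best split agrees with exhaustive hand enumeration", {
  res <- findBestSplit(cbind(c(1, 2, 3, 4)),
                       standardizeNodeResponses(c(-1, -1, 1, 1)))
  expect_equal(res$splitVar, 1)
  expect_equal(res$splitValue, 2.5)
  expect_equal(res$gqStar, 4)

  # constant predictors admit no split
  expect_null(findBestSplit(cbind(rep(2, 6)),
                            standardizeNodeResponses(rnorm(6))))
})

test_that("split search equals the brute-force SS minimizer", {
  # the maximized reduced criterion and the minimized raw criterion
  # (summed within-daughter SS) must choose the same split
  set.seed(100)
  for (rep in 1:200) {
    nt <- sample(4:12, 1)
    p <- sample(1:4, 1)
    q <- sample(1:3, 1)
    Xn <- matrix(sample(1:6, nt * p, replace = TRUE) + 0, nt, p)
    Yn <- matrix(rnorm(nt * q), nt, q)
    Ys <- standardizeNodeResponses(Yn)
    got <- findBestSplit(Xn, Ys, nodesize = 1)
    want <- bruteForceBestSplit(Xn, Ys, nodesize = 1)
    if (is.null(want)) {
      expect_null(got)
    } else {
      # the returned split must attain the brute-force optimum; distinct
      # (var, cut) pairs inducing the same partition tie exactly
      left <- which(Xn[, got$splitVar] <= got$splitValue)
      right <- setdiff(seq_len(nt), left)
      ssGot <- 0
      for (j in seq_len(ncol(Ys))) {
        ssGot <- ssGot +
          sum((Ys[left, j] - mean(Ys[left, j]))^2) +
          sum((Ys[right, j] - mean(Ys[right, j]))^2)
      }
      expect_equal(ssGot, want$ss, tolerance = 1e-9)
      # and the reported criterion is consistent with its own G vector
      expect_equal(got$gqStar, sum(got$G), tolerance = 1e-8)
    }
  }
})

test_that("MSRV is the argmax with smallest-index ties", {
  expect_equal(identifyMsrv(c(0.1, 0.9, 0.3)), 2L)
  expect_equal(identifyMsrv(c(0.5, 0.5)), 1L)
  expect_equal(identifyMsrv(0.7), 1L)
  expect_error(identifyMsrv(numeric(0)), "empty")
})

test_that("trees bookkeep depths, partitions, and bags", {
  sim <- smallLatentSim(seed = 21)
  fit <- smallForest(sim, ntree = 10, seed = 21)
  X <- datasets(sim)[[1]]
  for (b in seq_len(nTrees(fit))) {
    tr <- fit@trees[[b]]
    bag <- treeBagIndices(fit, b)
    expect_identical(sort(c(bag$inbag, bag$oob)), seq_len(fit@n))
    expect_identical(sum(bag$counts), fit@n)
    expect_equal(tr$depth[1], 0L)
    internal <- which(!is.na(tr$splitVar))
    # terminal <=> no split var <=> no msrv
    expect_identical(is.na(tr$splitVar), is.na(tr$msrv))
    for (nd in internal) {
      expect_equal(tr$depth[tr$left[nd]], tr$depth[nd] + 1L)
      expect_equal(tr$depth[tr$right[nd]], tr$depth[nd] + 1L)
      expect_equal(tr$nNode[tr$left[nd]] + tr$nNode[tr$right[nd]],
                   tr$nNode[nd])
    }
    # re-drop the in-bag multiset and check the recorded partition sizes
    node <- rep(1L, fit@n)
    counts <- bag$counts
    sizes <- integer(length(tr$depth))
    recurse <- function(ids, nd) {
      sizes[nd] <<- sum(counts[ids])
      if (is.na(tr$splitVar[nd])) {
        return()
      }
      left <- ids[X[ids, tr$splitVar[nd]] <= tr$splitValue[nd]]
      recurse(left, tr$left[nd])
      recurse(setdiff(ids, left), tr$right[nd])
    }
    recurse(which(counts > 0L), 1L)
    expect_identical(sizes, tr$nNode)
  }
})

test_that("a single scored response is always the MSRV", {
  sim <- smallLatentSim(seed = 5)
  Y1 <- datasets(sim)[[2]][, 1, drop = FALSE]
  fit <- mrfForest(datasets(sim)[[1]], Y1, forestParams(ntree = 5, seed = 5))
  for (tr in fit@trees) {
    expect_true(all(tr$msrv[!is.na(tr$msrv)] == 1L))
  }
})

test_that("forests are deterministic and schedule-independent", {
  sim <- smallLatentSim(seed = 31)
  X <- datasets(sim)[[1]]
  Y <- datasets(sim)[[2]]
  f1 <- mrfForest(X, Y, forestParams(ntree = 8, seed = 31))
  f2 <- mrfForest(X, Y, forestParams(ntree = 8, seed = 31))
  expect_identical(f1@trees, f2@trees)
  # tree b of a forest is the stand-alone tree with the same stream index
  t3 <- growTree(X, Y, forestParams(ntree = 8, seed = 31),
                 treeSeed = 31, treeIndex = 2L)
  expect_identical(t3@trees[[1]], f1@trees[[3]])
  # a different seed gives a different forest
  f4 <- mrfForest(X, Y, forestParams(ntree = 8, seed = 32))
  expect_false(identical(f1@trees, f4@trees))
})

test_that("degenerate and invalid inputs are handled", {
  X <- matrix(rnorm(8), 4, 2)
  Y <- matrix(rnorm(8), 4, 2)
  # n < 2 * nodesize: single-root trees
  fit <- mrfForest(X, Y, forestParams(ntree = 3, nodesize = 5, seed = 1))
  for (tr in fit@trees) expect_length(tr$depth, 1L)
  expect_error(mrfForest(X, Y[1:3, ]), "same number of samples")
  Xna <- X
  Xna[1, 1] <- NA
  expect_error(mrfForest(Xna, Y), "missing")
})

test_that("benchmark-scale forests grow nontrivial labelled trees", {
  sim <- simulateLatent(latentScenario(200, c(500, 500), c(30, 30), seed = 6))
  fit <- mrfForest(datasets(sim)[[1]], datasets(sim)[[2]],
                   forestParams(ntree = 5, seed = 6))
  for (tr in fit@trees) {
    expect_gt(max(tr$depth), 0L)
    msrv <- tr$msrv[!is.na(tr$msrv)]
    expect_true(all(msrv >= 1L & msrv <= 500L))
  }
})
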