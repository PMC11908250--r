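test_that("weight normalization gives unit energy and preserves zeros", {
  expect_equal(normalizeWeights(c(3, 4, 0)), c(0.6, 0.8, 0))
  expect_equal(normalizeWeights(1), 1)
  set.seed(42)
  w <- normalizeWeights(runif(50, -1, 1))
  expect_equal(sum(w^2), 1, tolerance = 1e-12)
  expect_error(normalizeWeights(c(0, 0)), "degenerate")
})

test_that("latent generator standardizes, marks truth, and reproduces", {
  scn <- latentScenario(100, c(200, 200), c(20, 20), seed = 3)
  sim <- simulateLatent(scn)
  expect_length(datasets(sim), 2)
  for (tag in names(datasets(sim))) {
    M <- datasets(sim)[[tag]]
    expect_equal(dim(M), c(100, 200))
    expect_lt(max(abs(colMeans(M))), 1e-9)
    expect_lt(max(abs(apply(M, 2, sd) - 1)), 1e-9)
    expect_identical(sum(truthMask(sim)[[tag]]), 20L)
    expect_true(all(which(truthMask(sim)[[tag]]) == 1:20))
  }
  sim2 <- simulateLatent(scn)
  expect_identical(datasets(sim), datasets(sim2))
})

test_that("S2-style scenario has the documented shape", {
  sim <- simulateLatent(latentScenario(50, c(500, 500), c(30, 30), seed = 9))
  expect_equal(sapply(datasets(sim), ncol), c(omics1 = 500, omics2 = 500))
  expect_equal(sapply(truthMask(sim), sum), c(omics1 = 30, omics2 = 30))
})

test_that("noiseless identity-kernel latent data is exactly rank one", {
  scn <- latentScenario(40, c(10, 10), c(4, 4),
    noiseSd = 0, kernels = c("identity", "identity"), seed = 7
  )
  sim <- simulateLatent(scn)
  A <- datasets(sim)$omics1[, 1:4]
  B <- datasets(sim)$omics2[, 1:4]
  cors <- abs(cor(cbind(A, B)))
  expect_equal(unname(cors), matrix(1, 8, 8), tolerance = 1e-9)
})

test_that("latent cross-correlation links true columns across datasets", {
  sim <- simulateLatent(latentScenario(2000, c(20, 20), c(5, 5), seed = 11))
  A <- datasets(sim)$omics1
  B <- datasets(sim)$omics2
  crossTrue <- abs(cor(A[, 1:5], B[, 1:5]))
  crossNoise <- cor(A[, 6:20], B[, 6:20])
  expect_gt(min(apply(crossTrue, 1, max)), 0.15)
  expect_lt(max(abs(colMeans(crossNoise))), 0.05)
})

test_that("invalid latent scenarios are rejected", {
  expect_error(latentScenario(10, c(5, 5), c(6, 2)), "pc")
  expect_error(latentScenario(10, 5, 2), "datasets")
  expect_error(
    latentScenario(10, c(5, 5), c(2, 2), kernels = c("cube", "exp")),
    "kernels"
  )
})

test_that("non-linear generator has the derived column counts and truth", {
  sim <- simulateNonlinear(nonlinearScenario(50, p2c = 3, g = 1, seed = 2))
  expect_equal(ncol(datasets(sim)$omics1), 6) # pl = 2 * p2c
  expect_equal(ncol(datasets(sim)$omics2), 3)
  expect_true(all(unlist(truthMask(sim))))

  sim2 <- simulateNonlinear(
    nonlinearScenario(30, p2c = 5, g = 3, pd1 = 7, pd2 = 4, seed = 2)
  )
  expect_equal(ncol(datasets(sim2)$omics1), 3 * 10 + 7) # g * pl + pd1
  expect_equal(sum(truthMask(sim2)$omics1), 30)
  expect_equal(sum(truthMask(sim2)$omics2), 5)
  expect_lt(max(abs(colMeans(datasets(sim2)$omics1))), 1e-9)
})

test_that("group noise scale decays the correlation with the basis", {
  scn <- nonlinearScenario(2000, p2c = 3, g = 4, seed = 13)
  sim <- simulateNonlinear(scn)
  set.seed(13)
  U <- matrix(rnorm(2000 * 6), 2000, 6) # regenerate the shared basis
  X <- datasets(sim)$omics1
  firstCopy <- abs(diag(cor(U, X[, (0:5) * 4 + 1])))
  lastCopy <- abs(diag(cor(U, X[, (0:5) * 4 + 4])))
  expect_true(all(firstCopy > lastCopy))
  expect_gt(min(firstCopy), 0.99) # noise scale 0.01 on the first copy
})

test_that("stride-3 basis indexing is available behind the flag", {
  sim <- simulateNonlinear(
    nonlinearScenario(40, p2c = 3, g = 1, seed = 4, basisIndexing = "stride3")
  )
  expect_equal(ncol(datasets(sim)$omics2), 3)
})
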