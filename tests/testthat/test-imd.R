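test_that("inverse minimal depth follows the worked values", {
  expect_equal(inverseMinimalDepth(0), 1)
  expect_equal(inverseMinimalDepth(1), 1 / 2)
  expect_equal(inverseMinimalDepth(NA), 0)
  expect_equal(inverseMinimalDepth(c(0, 1, 3, NA)), c(1, 0.5, 0.25, 0))
  expect_error(inverseMinimalDepth(-1), "negative")
})

test_that("tree minimal depths take the shallowest appearance", {
  sim <- smallLatentSim(seed = 41)
  fit <- smallForest(sim, ntree = 5, seed = 41)
  for (b in 1:5) {
    tr <- fit@trees[[b]]
    internal <- which(!is.na(tr$splitVar))
    md <- treeMinimalDepths(fit, b, "predictor")
    for (v in names(md)) {
      depths <- tr$depth[internal][tr$splitVar[internal] == as.integer(v)]
      expect_equal(unname(md[v]), min(depths))
    }
    # the root split variable always has minimal depth 0
    expect_equal(unname(md[as.character(tr$splitVar[1])]), 0L)
    mdr <- treeMinimalDepths(fit, b, "response")
    expect_true(all(as.integer(names(mdr)) %in% tr$msrv[internal]))
  }
})

test_that("forest IMD averages per-tree values with zeros for absences", {
  # three hand-built depth patterns: depth 0, depth 1, absent
  M <- rbind(c(1, 0), c(0.5, 0), c(0, 1))
  prof <- momirf:::profileFromMatrix(M, "predictor", c("a", "b"))
  expect_equal(forestImd(prof), c(a = 0.5, b = 1 / 3))
  expect_equal(prof@mu, mean(c(0.5, 1 / 3)))

  # always selected at the root: IMD 1, se 0, t-score +Inf
  M2 <- cbind(rep(1, 4), rep(0, 4))
  p2 <- momirf:::profileFromMatrix(M2, "predictor", c("a", "b"))
  expect_equal(unname(forestImd(p2)), c(1, 0))
  expect_equal(p2@se, c(0, 0))
  expect_identical(unname(tscoreImd(p2)), c(Inf, -Inf))
})

test_that("profiles match per-tree recomputation on a real forest", {
  sim <- smallLatentSim(seed = 51)
  fit <- smallForest(sim, ntree = 12, seed = 51)
  prof <- imdProfiles(fit)
  M <- perTreeImd(prof$response)
  expect_equal(dim(M), c(12, fit@q))
  for (b in c(1L, 7L)) {
    md <- treeMinimalDepths(fit, b, "response")
    want <- numeric(fit@q)
    want[as.integer(names(md))] <- 1 / (md + 1)
    expect_equal(unname(M[b, ]), want)
  }
  expect_equal(prof$response@forestImd, unname(colMeans(M)))
  expect_equal(
    prof$response@se,
    unname(apply(M, 2, sd) / sqrt(12))
  )
  # t-score is zero at the grand mean and increasing in forest IMD
  ts <- tscoreImd(prof$response)
  fi <- forestImd(prof$response)
  expect_true(all(ts[fi > prof$response@mu] > 0, na.rm = TRUE))
  expect_true(all(ts[fi < prof$response@mu] < 0, na.rm = TRUE))
})

test_that("weak-variable depth distribution matches closed forms", {
  expect_equal(weakMdPmf(1, 0), 1)
  expect_equal(weakMdPmf(2, 0), 0.5)
  # in high dimension every depth probability collapses toward zero
  # (P(D = d) ~ 2^d / p, so ~1e-3 at d = 10, p = 1e6)
  expect_true(all(weakMdPmf(1e6, 0:10) < 2e-3))
  expect_lt(sum(weakMdPmf(1e6, 0:10)), 3e-3)
})

test_that("general depth distribution reduces and sums to one", {
  expect_equal(mdPmf(c(1, 0.5), c(1, 2), 0), 1)
  expect_equal(mdPmf(c(0, 0, 0), c(1, 2, 4), 2), 0)
  # pi * theta = 1/p with balanced node counts reduces to the weak form
  p <- 7
  D <- 6
  piTheta <- rep(1 / p, D)
  ell <- 2^(0:(D - 1))
  for (d in 0:(D - 1)) {
    expect_equal(mdPmf(piTheta, ell, d), weakMdPmf(p, d))
  }
  # completeness: depth mass plus never-selected mass is 1
  mass <- sum(vapply(0:(D - 1), function(d) mdPmf(piTheta, ell, d),
                     numeric(1)))
  never <- prod((1 - 1 / p)^ell)
  expect_equal(mass + never, 1)
  # IMD change of variable
  expect_equal(imdPmf(piTheta, ell, 1), weakMdPmf(p, 0))
  expect_equal(imdPmf(piTheta, ell, 1 / 3), weakMdPmf(p, 2))
})

test_that("true variables dominate the IMD ranking on latent data", {
  sim <- simulateLatent(latentScenario(150, c(120, 120), c(12, 12), seed = 61))
  fit <- mrfForest(datasets(sim)[[1]], datasets(sim)[[2]],
                   forestParams(ntree = 60, seed = 61))
  prof <- imdProfiles(fit)
  for (side in c("predictor", "response")) {
    fi <- forestImd(prof[[side]])
    expect_gt(mean(fi[1:12]), 2 * mean(fi[-(1:12)]))
  }
  # noise t-scores centre below zero
  ts <- tscoreImd(prof$response)[-(1:12)]
  expect_lt(median(ts[is.finite(ts)]), 0)
})
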