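test_that("PCA reduction honours the cumulative variance target", {
  set.seed(12)
  u <- rnorm(30)
  rank1 <- tcrossprod(u, runif(15))
  expect_equal(ncol(pcaReduce(rank1, 0.5)), 1)
  expect_equal(ncol(pcaReduce(rank1, 1)), 1)

  M <- matrix(rnorm(100 * 50), 100, 50)
  full <- pcaReduce(M, 1)
  expect_equal(ncol(full), 50)
  part <- pcaReduce(M, 0.8)
  ev <- prcomp(M)$sdev^2
  expect_equal(ncol(part), which(cumsum(ev) / sum(ev) >= 0.8)[1])
  expect_error(pcaReduce(matrix(1, 10, 3)), "constant")
})

test_that("direction search recovers a planted dependency", {
  set.seed(13)
  n <- 80
  B <- matrix(rnorm(n * 12), n, 12)
  # A is a noisy function of B's leading columns, B is not a function of A
  A <- cbind(
    B[, 1] + 0.2 * rnorm(n), B[, 1] - B[, 2] + 0.2 * rnorm(n),
    B[, 2] + 0.2 * rnorm(n), 0.5 * B[, 1] + 0.2 * rnorm(n)
  )
  dsets <- list(
    A = momirf:::standardizeColumns(A),
    B = momirf:::standardizeColumns(B)
  )
  colnames(dsets$A) <- paste0("a", 1:4)
  colnames(dsets$B) <- paste0("b", 1:12)
  models <- chooseDirections(dsets, forestParams(ntree = 30, seed = 13))
  expect_length(models, 2)
  tags <- vapply(models, function(m) m@responseTag, character(1))
  expect_setequal(tags, c("A", "B"))
  mA <- models[[which(tags == "A")]]
  mB <- models[[which(tags == "B")]]
  expect_identical(mA@predictorTag, "B")
  # predicting A from B is easier than the reverse
  expect_lt(mA@meanOob, mB@meanOob)
  expect_error(
    chooseDirections(list(A = dsets$A, B = dsets$B[1:40, ]),
                     forestParams(ntree = 5)),
    "same samples"
  )
})

test_that("aggregation averages IMD over the models a dataset appears in", {
  sim <- smallLatentSim(seed = 141)
  dsets <- datasets(sim)
  models <- chooseDirections(dsets, forestParams(ntree = 20, seed = 141))
  meanImd <- momirf:::meanImdProfiles(models)
  expect_setequal(names(meanImd), names(dsets))
  # each dataset appears once as response and once as predictor (K = 2)
  profs <- lapply(models, function(m) imdProfiles(m@forest))
  tags <- vapply(models, function(m) m@responseTag, character(1))
  for (tag in names(dsets)) {
    asResp <- forestImd(profs[[which(tags == tag)]]$response)
    asPred <- forestImd(profs[[which(tags != tag)]]$predictor)
    expect_equal(meanImd[[tag]], (asResp + asPred) / 2)
  }
  expect_true(all(unlist(meanImd) >= 0 & unlist(meanImd) <= 1))
})

test_that("per-dataset selections obey the method rules", {
  sim <- simulateLatent(latentScenario(70, c(40, 40), c(8, 8), seed = 151))
  dsets <- datasets(sim)
  models <- chooseDirections(dsets, forestParams(ntree = 40, seed = 151))
  selT <- aggregateAndSelect(models, dsets, "transformation")
  expect_setequal(names(selT), names(dsets))
  # majority rule: a variable must be selected in > half of its models
  votes <- selT$omics1@diagnostics$votes
  total <- selT$omics1@diagnostics$models
  expect_setequal(
    selectedIds(selT$omics1),
    names(votes)[votes > total / 2]
  )
  selM <- aggregateAndSelect(models, dsets, "mixture")
  for (tag in names(dsets)) {
    expect_true(all(selectedIds(selM[[tag]]) %in% colnames(dsets[[tag]])))
  }
  res <- integrateOmics(dsets, forestParams(ntree = 40, seed = 151),
                        method = "mixture")
  expect_s4_class(res, "IntegrationResult")
  expect_identical(
    selectedIds(res@selections$omics1),
    selectedIds(selM$omics1)
  )
})

test_that("integration is deterministic under a fixed master seed", {
  sim <- smallLatentSim(seed = 161)
  r1 <- integrateOmics(datasets(sim), forestParams(ntree = 15, seed = 161),
                       method = "transformation")
  r2 <- integrateOmics(datasets(sim), forestParams(ntree = 15, seed = 161),
                       method = "transformation")
  expect_identical(
    lapply(r1@selections, selectedIds),
    lapply(r2@selections, selectedIds)
  )
})
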