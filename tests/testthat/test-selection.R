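test_that("filter threshold keeps exactly the IMD exceedances", {
  M <- rbind(
    c(0.5, 0.3, 0.02, 0, 0.01),
    c(0.4, 0.2, 0.00, 0, 0.03)
  )
  prof <- momirf:::profileFromMatrix(M, "predictor", letters[1:5])
  sdv <- sd(prof@forestImd)
  expect_identical(filterThreshold(prof, 0), c("a", "b", "c", "e"))
  expect_identical(
    filterThreshold(prof, 1),
    letters[1:5][prof@forestImd > sdv]
  )
  # kept sets shrink monotonically in tau
  sizes <- vapply(seq(0, 3, by = 0.25),
                  function(t) length(filterThreshold(prof, t)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("filter tuning recovers a constructed strong set", {
  # signal variables with high IMD and real predictive structure
  sim <- simulateLatent(latentScenario(80, c(40, 40), c(8, 8), seed = 111))
  X <- datasets(sim)[[1]]
  Y <- datasets(sim)[[2]]
  fit <- mrfForest(X, Y, forestParams(ntree = 50, seed = 111))
  sel <- selectFilter(fit, X, Y, kRepeats = 2L, refitNtree = 50L)
  expect_s4_class(sel$predictor, "SelectionResult")
  keptP <- selectedIds(sel$predictor)
  keptQ <- selectedIds(sel$response)
  # most of the kept set is true signal and most signal is kept
  trueP <- names(which(truthMask(sim)[[1]]))
  expect_gt(length(intersect(keptP, trueP)), 5)
  expect_lt(length(keptP), 25)
  curve <- sel$predictor@diagnostics$oobCurve
  expect_true(all(diff(curve$sizePredictor) <= 0))
  expect_identical(keptQ, sel$response@selectedIds)
})

test_that("zero-inflated mixture recovers planted parameters", {
  set.seed(7)
  nz <- 4900
  n1 <- round(0.7 * nz)
  x <- c(
    rep(0, 2100), # 30% exact zeros
    rnorm(n1, 0.05, 0.01),
    rnorm(nz - n1, 0.4, 0.05)
  )
  x <- pmin(pmax(x, 0.001), 1)
  x[seq_len(2100)] <- 0
  fit <- fitMixture(x)
  expect_equal(fit@p0, 0.3)
  expect_equal(fit@p, 0.7, tolerance = 0.02)
  expect_equal(fit@mu1, 0.05, tolerance = 0.02)
  expect_equal(fit@mu2, 0.40, tolerance = 0.02)
  expect_true(fit@converged)
  # EM guarantee: the modified log-likelihood never decreases
  expect_true(all(diff(fit@loglikTrace) > -1e-8))
})

test_that("mixture labelling, errors, and the truncated variant behave", {
  set.seed(8)
  x <- c(rep(0, 20), rnorm(200, 0.08, 0.02), rnorm(60, 0.5, 0.08))
  x <- pmin(pmax(x, 1e-4), 1)
  x[1:20] <- 0
  g <- fitMixture(x, "gaussian")
  expect_lte(g@mu1, g@mu2) # component 1 is the noise component
  tr <- fitMixture(x, "truncated_normal")
  expect_s4_class(tr, "MixtureFit")
  expect_true(all(diff(tr@loglikTrace) > -1e-6))
  expect_error(fitMixture(c(rep(0, 30), 0.5, 0.6)), "fewer than 10")
  expect_error(fitMixture(c(-0.1, 0.5)), "not")
})

test_that("posteriors sum to one and zeros belong to the zero mass", {
  set.seed(9)
  x <- c(rep(0, 15), runif(100, 0.01, 0.2), runif(40, 0.3, 0.6))
  fit <- fitMixture(x)
  post <- posteriorProbs(fit, x)
  expect_equal(unname(rowSums(post)), rep(1, length(x)), tolerance = 1e-12)
  expect_equal(post[x == 0, "Pr0"], rep(1, 15))
  expect_equal(post[x > 0, "Pr0"], rep(0, 140))
  # far in the upper tail the signal component wins
  expect_gt(posteriorProbs(fit, 0.9)[, "Pr2"], 0.999)
})

test_that("mixture selection picks the upper mode and honours pr bounds", {
  M <- rbind(
    c(rep(0.04, 30), rep(0.5, 10), rep(0, 10)),
    c(rep(0.06, 30), rep(0.4, 10), rep(0, 10))
  )
  M <- M + matrix(seq(0, 0.01, length.out = 100), 2, 50, byrow = TRUE)
  M[, 41:50] <- 0
  M[M > 1] <- 1
  prof <- momirf:::profileFromMatrix(M, "response", sprintf("v%02d", 1:50))
  sel <- selectMixture(prof, pr = 0.05)
  expect_setequal(selectedIds(sel), sprintf("v%02d", 31:40))
  expect_length(selectedIds(selectMixture(prof, pr = 0)), 0)
  allNonzero <- featureIds(prof)[prof@forestImd > 0]
  expect_setequal(selectedIds(selectMixture(prof, pr = 1)), allNonzero)
})

test_that("t-score selection uses the Student quantile at B - 1 df", {
  sim <- smallLatentSim(seed = 121)
  fit <- smallForest(sim, ntree = 100, seed = 121)
  prof <- imdProfiles(fit)
  sel <- selectTransformation(prof$predictor, alpha = 0.05)
  expect_equal(unname(sel@threshold), qt(0.95, 99))
  expect_equal(unname(sel@threshold), 1.6604, tolerance = 1e-4)
  ts <- tscoreImd(prof$predictor)
  expect_setequal(selectedIds(sel),
                  names(ts)[!is.na(ts) & ts > qt(0.95, 99)])
  # a variable sitting exactly at the grand mean is never selected
  expect_false(any(ts[selectedIds(sel)] == 0))
  low <- selectTransformation(prof$predictor, tail = "lower")
  expect_gte(length(selectedIds(low)), length(selectedIds(sel)))
})

test_that("transformation is conservative on pure-noise data", {
  sim <- simulateLatent(
    latentScenario(60, c(60, 60), c(0, 0), seed = 131)
  )
  fit <- mrfForest(datasets(sim)[[1]], datasets(sim)[[2]],
                   forestParams(ntree = 100, seed = 131))
  prof <- imdProfiles(fit)
  frac <- length(selectedIds(selectTransformation(prof$response))) / 60
  expect_lte(frac, 0.15)
})
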