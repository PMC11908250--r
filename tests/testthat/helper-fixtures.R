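# small shared fixtures, built in code

smallLatentSim <- function(seed = 1, n = 60, p = c(30, 30), pc = c(5, 5)) {
  simulateLatent(latentScenario(n, p, pc, seed = seed))
}

smallForest <- function(sim, ntree = 25, seed = 1, ...) {
  mrfForest(
    datasets(sim)[[1]], datasets(sim)[[2]],
    forestParams(ntree = ntree, seed = seed, ...)
  )
}

# brute-force reference: minimize the summed within-daughter sum of
# squares (the raw multivariate criterion) over every (variable, cut)
# pair; ties broken by smallest variable, then smallest cut
bruteForceBestSplit <- function(Xnode, Ystar, nodesize = 1) {
  nt <- nrow(Xnode)
  best <- NULL
  for (v in seq_len(ncol(Xnode))) {
    cuts <- sort(unique(Xnode[, v]))
    if (length(cuts) < 2) next
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (cut in mids) {
      left <- which(Xnode[, v] <= cut)
      right <- setdiff(seq_len(nt), left)
      if (length(left) < nodesize || length(right) < nodesize) next
      ss <- 0
      for (j in seq_len(ncol(Ystar))) {
        yl <- Ystar[left, j]
        yr <- Ystar[right, j]
        ss <- ss + sum((yl - mean(yl))^2) + sum((yr - mean(yr))^2)
      }
      if (is.null(best) || ss < best$ss - 1e-9) {
        best <- list(var = v, cut = cut, ss = ss)
      }
    }
  }
  best
}

# reference average precision by explicit enumeration over recall steps
bruteForceAp <- function(scores, truth) {
  ord <- order(-scores, truth)
  pos <- truth[ord]
  P <- sum(truth)
  ap <- 0
  tp <- 0
  for (k in seq_along(pos)) {
    if (pos[k]) {
      tp <- tp + 1
      ap <- ap + tp / k
    }
  }
  ap / P
}
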