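#' @include forest.R
NULL

# terminal node id of every sample in every tree (n x B)
terminalAssignments <- function(forest, X) {
  .forest_assign_cpp(forest@trees, X)
}

#' Out-of-bag error of the response variables
#'
#' For each sample i, the OOB prediction of response j averages, over the
#' trees where i is out of bag, the in-bag mean of Y_j in the terminal
#' node i falls into. The per-response error is the mean squared
#' difference over samples covered by at least one OOB tree; uncovered
#' samples are excluded (their count is reported in the `"nExcluded"`
#' attribute).
#'
#' `Y` may contain more columns than the forest was grown on (on the same
#' samples): terminal-node means exist for any column, which is how the
#' filter tuning scores all original variables from a reduced refit.
#'
#' @param forest an [MrfForest-class] grown on (X, Y).
#' @param X the training predictor matrix (columns must match the fit).
#' @param Y response columns to score.
#' @return named numeric vector of per-response OOB errors.
#' @export
responseOobError <- function(forest, X, Y) {
  checkMatrixPair(X, Y)
  n <- nrow(X)
  term <- terminalAssignments(forest, X)
  predSum <- matrix(0, n, ncol(Y))
  cnt <- numeric(n)
  for (b in seq_along(forest@trees)) {
    inb <- forest@trees[[b]]$inbag
    oob <- inb == 0L
    if (!any(oob)) next
    tb <- term[, b]
    wsum <- rowsum(Y * inb, tb)
    wn <- rowsum(inb, tb)
    tm <- wsum / as.vector(wn)
    rows <- match(tb[oob], as.integer(rownames(wsum)))
    predSum[oob, ] <- predSum[oob, ] + tm[rows, , drop = FALSE]
    cnt[oob] <- cnt[oob] + 1
  }
  covered <- cnt > 0
  if (!any(covered)) {
    stop("forest has zero out-of-bag coverage; increase ntree")
  }
  pred <- predSum[covered, , drop = FALSE] / cnt[covered]
  err <- colMeans((Y[covered, , drop = FALSE] - pred)^2)
  names(err) <- if (ncol(Y) == forest@q) forest@responseIds else colnames(Y)
  attr(err, "nExcluded") <- sum(!covered)
  err
}

#' Forest-weights prediction of the predictor matrix
#'
#' OOB prediction of X from the forest weights: for an OOB sample i, the
#' weight of training sample k accumulates, over the trees where i is out
#' of bag, the in-bag multiplicity of k in the terminal node shared with
#' i; weights are then normalized to sum to 1 and the prediction is the
#' weighted average of the rows of X.
#'
#' @param forest an [MrfForest-class].
#' @param X the training predictor matrix (columns must match the fit;
#'   used to drop samples down the trees).
#' @param values matrix whose columns are predicted as the weighted
#'   average of training rows (default `X` itself); may have any number
#'   of columns, which lets a reduced refit predict all original
#'   predictors.
#' @param keepWeights return the n x n weight matrix in the `"weights"`
#'   attribute (for diagnostics).
#' @return n x ncol(values) matrix of predictions; rows for samples never
#'   out of bag are `NA` and flagged in the logical `"covered"` attribute.
#' @export
predictorOobPredict <- function(forest, X, values = X,
                                keepWeights = FALSE) {
  n <- nrow(X)
  term <- terminalAssignments(forest, X)
  if (keepWeights) {
    # explicit weight matrix (diagnostics); the fast path below is the
    # algebraically identical pooled-then-normalized form
    W <- matrix(0, n, n)
    for (b in seq_along(forest@trees)) {
      inb <- forest@trees[[b]]$inbag
      oob <- inb == 0L
      if (!any(oob)) next
      tb <- term[, b]
      for (t in unique(tb[oob])) {
        members <- which(tb == t & !oob)
        rows <- which(tb == t & oob)
        if (length(members) == 0L) next
        W[rows, members] <- W[rows, members] +
          rep(inb[members], each = length(rows))
      }
    }
    rs <- rowSums(W)
    covered <- rs > 0
    W[covered, ] <- W[covered, , drop = FALSE] / rs[covered]
    pred <- matrix(NA_real_, n, ncol(values), dimnames = dimnames(values))
    pred[covered, ] <- W[covered, , drop = FALSE] %*% values
    attr(pred, "covered") <- covered
    attr(pred, "weights") <- W
    return(pred)
  }
  # pooled co-occupancy weights collapse to per-terminal in-bag-weighted
  # sums accumulated over the sample's OOB trees
  predSum <- matrix(0, n, ncol(values))
  wSum <- numeric(n)
  for (b in seq_along(forest@trees)) {
    inb <- forest@trees[[b]]$inbag
    oob <- inb == 0L
    if (!any(oob)) next
    tb <- term[, b]
    tsum <- rowsum(values * inb, tb)
    tcnt <- rowsum(inb, tb)
    rows <- match(tb[oob], as.integer(rownames(tsum)))
    predSum[oob, ] <- predSum[oob, ] + tsum[rows, , drop = FALSE]
    wSum[oob] <- wSum[oob] + tcnt[rows]
  }
  covered <- wSum > 0
  pred <- matrix(NA_real_, n, ncol(values), dimnames = dimnames(values))
  pred[covered, ] <- predSum[covered, , drop = FALSE] / wSum[covered]
  attr(pred, "covered") <- covered
  pred
}

#' Out-of-bag error of the predictor variables
#'
#' Mean squared difference between X and its forest-weights OOB prediction
#' (see [predictorOobPredict()]), per column, over covered samples.
#'
#' @inheritParams predictorOobPredict
#' @return named numeric vector of per-predictor OOB errors (one per
#'   column of `values`).
#' @export
predictorOobError <- function(forest, X, values = X) {
  pred <- predictorOobPredict(forest, X, values)
  covered <- attr(pred, "covered")
  if (!any(covered)) {
    stop("forest has zero out-of-bag coverage; increase ntree")
  }
  err <- colMeans(
    (values[covered, , drop = FALSE] - pred[covered, , drop = FALSE])^2
  )
  names(err) <- if (ncol(values) == forest@p) {
    forest@predictorIds
  } else {
    colnames(values)
  }
  attr(err, "nExcluded") <- sum(!covered)
  err
}

#' Full out-of-bag report
#'
#' Computes the per-response errors, the per-predictor (forest-weights)
#' errors, and their mean over all p + q variables, which is the tuning
#' criterion of the filter selection rule and the ranking criterion of
#' the multi-omics direction search.
#'
#' @inheritParams responseOobError
#' @return an [OobReport-class].
#' @examples
#' sim <- simulateLatent(latentScenario(50, c(20, 20), c(4, 4), seed = 2))
#' fit <- mrfForest(datasets(sim)$omics1, datasets(sim)$omics2,
#'                  forestParams(ntree = 20, seed = 2))
#' oobReport(fit, datasets(sim)$omics1, datasets(sim)$omics2)
#' @export
oobReport <- function(forest, X, Y) {
  respErr <- responseOobError(forest, X, Y)
  predErr <- predictorOobError(forest, X)
  new("OobReport",
    perResponseErr = respErr, perPredictorErr = predErr,
    meanErr = mean(c(respErr, predErr)),
    nCovered = as.integer(
      nrow(X) - max(attr(respErr, "nExcluded"), attr(predErr, "nExcluded"))
    )
  )
}
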