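#' @include AllClasses.R
NULL

checkMatrixPair <- function(X, Y) {
  stopifnot(is.matrix(X), is.matrix(Y), is.numeric(X), is.numeric(Y))
  if (nrow(X) != nrow(Y)) {
    stop("X and Y must have the same number of samples (rows)")
  }
  if (anyNA(X) || anyNA(Y)) {
    stop("missing values are not supported; remove incomplete features")
  }
}

resolveMtry <- function(params, p) {
  mtry <- params@mtry
  if (is.na(mtry)) mtry <- ceiling(p / 3)
  min(as.integer(mtry), p)
}

featureIdsOf <- function(M, prefix) {
  ids <- colnames(M)
  if (is.null(ids)) ids <- paste0(prefix, seq_len(ncol(M)))
  ids
}

#' Grow a multivariate random forest
#'
#' Fits `ntree` bootstrap trees of X (predictors) against Y (responses)
#' with the summed split criterion over per-node standardized responses.
#' Every internal node records the maximal splitting response variable
#' (MSRV): the response with the largest per-response split statistic at
#' that split. Per-tree random streams are derived deterministically from
#' `params@seed`, so two fits with the same inputs are identical.
#'
#' @param X numeric samples x predictors matrix (no missing values).
#' @param Y numeric samples x responses matrix on the same samples.
#' @param params a [ForestParams-class]; see [forestParams()].
#' @return an [MrfForest-class].
#' @examples
#' sim <- simulateLatent(latentScenario(60, c(30, 30), c(5, 5), seed = 1))
#' fit <- mrfForest(datasets(sim)$omics1, datasets(sim)$omics2,
#'                  forestParams(ntree = 10, seed = 1))
#' fit
#' @export
mrfForest <- function(X, Y, params = forestParams()) {
  checkMatrixPair(X, Y)
  validObject(params)
  mtry <- resolveMtry(params, ncol(X))
  maxDepth <- if (is.na(params@maxDepth)) 0L else params@maxDepth
  trees <- .grow_forest_cpp(
    X, Y, params@ntree, mtry, params@respFrac, params@nodesize,
    maxDepth, params@nsplit, params@seed
  )
  new("MrfForest",
    trees = trees, params = params, mtryUsed = mtry,
    n = nrow(X), p = ncol(X), q = ncol(Y),
    predictorIds = featureIdsOf(X, "X"),
    responseIds = featureIdsOf(Y, "Y")
  )
}

#' Grow a single multivariate tree
#'
#' Grows one bootstrap tree with its own seed; `treeIndex` selects the
#' derived stream so that `growTree(X, Y, params, params@seed, b - 1)`
#' reproduces tree b of [mrfForest()] exactly.
#'
#' @inheritParams mrfForest
#' @param treeSeed integer seed for this tree.
#' @param treeIndex stream index mixed into the seed (default 0).
#' @return a single-tree [MrfForest-class].
#' @export
growTree <- function(X, Y, params = forestParams(), treeSeed = params@seed,
                     treeIndex = 0L) {
  checkMatrixPair(X, Y)
  mtry <- resolveMtry(params, ncol(X))
  maxDepth <- if (is.na(params@maxDepth)) 0L else params@maxDepth
  tree <- .grow_tree_cpp(
    X, Y, mtry, params@respFrac, params@nodesize, maxDepth,
    params@nsplit, as.integer(treeSeed), as.integer(treeIndex)
  )
  p1 <- params
  p1@ntree <- 1L
  p1@seed <- as.integer(treeSeed)
  new("MrfForest",
    trees = list(tree), params = p1, mtryUsed = mtry,
    n = nrow(X), p = ncol(X), q = ncol(Y),
    predictorIds = featureIdsOf(X, "X"),
    responseIds = featureIdsOf(Y, "Y")
  )
}

#' Standardize node responses to a 0-1 scale
#'
#' Within-node standardization used by the split criterion:
#' `y* = sqrt(n) (y - mean) / ||y - mean||`, so each column has mean 0 and
#' mean square 1 over the node. Zero-variance columns map to all zeros and
#' are flagged inert in the `"inert"` attribute.
#'
#' @param Y numeric node response submatrix (>= 2 rows) or vector.
#' @return the standardized matrix with a logical `"inert"` attribute.
#' @examples
#' standardizeNodeResponses(cbind(c(1, 2, 3))) # +- sqrt(3/2), 0
#' @export
standardizeNodeResponses <- function(Y) {
  if (is.vector(Y)) Y <- cbind(Y)
  n <- nrow(Y)
  if (is.null(n) || n == 0L) stop("empty node")
  if (n < 2L) stop("node must contain at least 2 samples")
  ctr <- sweep(Y, 2L, colMeans(Y), "-")
  ss <- colSums(ctr^2)
  inert <- ss <= 0
  out <- ctr
  out[, !inert] <- sweep(
    ctr[, !inert, drop = FALSE], 2L,
    sqrt(ss[!inert] / n), "/"
  )
  out[, inert] <- 0
  attr(out, "inert") <- unname(inert)
  out
}

#' Per-response split statistic
#'
#' For a standardized response column y* and a proposed daughter partition,
#' `Gj = (sum_L y*)^2 / nL + (sum_R y*)^2 / nR`: the algebraic reduction of
#' the summed within-daughter sum of squares, so larger values mean a
#' better split for that response.
#'
#' @param ystar standardized response values of the node.
#' @param leftIds,rightIds index vectors forming a non-empty disjoint
#'   partition of the node.
#' @return the nonnegative statistic Gj.
#' @examples
#' splitStatistic(c(-1, -1, 1, 1), 1:2, 3:4) # 4
#' @export
splitStatistic <- function(ystar, leftIds, rightIds) {
  if (length(leftIds) == 0L || length(rightIds) == 0L) {
    stop("both daughter nodes must be non-empty")
  }
  if (length(intersect(leftIds, rightIds)) > 0L ||
      length(union(leftIds, rightIds)) != length(ystar)) {
    stop("leftIds and rightIds must partition the node")
  }
  sum(ystar[leftIds])^2 / length(leftIds) +
    sum(ystar[rightIds])^2 / length(rightIds)
}

#' Find the best split of a node
#'
#' Searches all candidate predictors and admissible cut points (midpoints
#' of consecutive distinct sorted values, or `nsplit` random ones) for the
#' split maximizing the summed statistic over the given standardized
#' responses. Both daughters must contain at least `nodesize` samples.
#' Ties keep the smallest predictor index, then the smallest cut.
#'
#' @param Xnode node predictor submatrix.
#' @param Ystar node responses already standardized (see
#'   [standardizeNodeResponses()]); all given columns are scored.
#' @param candidateVars candidate predictor columns (default all).
#' @param nodesize minimum daughter size (default 1).
#' @param nsplit random cut count per candidate, 0 = exhaustive.
#' @param seed seed for random cuts (only used when `nsplit > 0`).
#' @return `NULL` if no admissible split exists, else a list with
#'   `splitVar`, `splitValue`, `G` (per-response statistics at the chosen
#'   split), and `gqStar` (their sum).
#' @examples
#' findBestSplit(cbind(1:4), standardizeNodeResponses(c(-1, -1, 1, 1)))
#' @export
findBestSplit <- function(Xnode, Ystar, candidateVars = seq_len(ncol(Xnode)),
                          nodesize = 1L, nsplit = 0L, seed = 1L) {
  Xnode <- as.matrix(Xnode)
  Ystar <- as.matrix(Ystar)
  stopifnot(nrow(Xnode) == nrow(Ystar))
  res <- .best_split_cpp(
    Xnode, Ystar, as.integer(candidateVars),
    as.integer(nodesize), as.integer(nsplit), as.integer(seed)
  )
  if (!isTRUE(res$found)) {
    return(NULL)
  }
  list(
    splitVar = res$splitVar, splitValue = res$splitValue,
    G = res$G, gqStar = res$gqStar
  )
}

#' Identify the maximal splitting response variable
#'
#' The MSRV of a split is the response with the largest per-response
#' statistic; ties are broken by the smallest index.
#'
#' @param G numeric vector of per-response split statistics.
#' @return the index of the maximal entry.
#' @examples
#' identifyMsrv(c(0.1, 0.9, 0.3)) # 2
#' @export
identifyMsrv <- function(G) {
  if (length(G) == 0L) stop("empty split statistic vector")
  which.max(G)
}

# in-bag count matrix (n x B)
inbagCounts <- function(forest) {
  vapply(forest@trees, function(tr) tr$inbag, integer(forest@n))
}

#' In-bag and out-of-bag sample indices of a tree
#'
#' @param forest an [MrfForest-class].
#' @param treeIndex which tree (1-based).
#' @return list with `inbag` (indices with multiplicity counts) and `oob`.
#' @export
treeBagIndices <- function(forest, treeIndex) {
  cnt <- forest@trees[[treeIndex]]$inbag
  list(
    inbag = which(cnt > 0L),
    counts = cnt,
    oob = which(cnt == 0L)
  )
}
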