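#' @include momirf-package.R
NULL

# ---------------------------------------------------------------- params ----

#' Forest growing parameters
#'
#' Container for the tuning parameters of a multivariate regression forest.
#' Construct with [forestParams()].
#'
#' @slot ntree number of bootstrap trees B.
#' @slot mtry number of candidate predictors per split; `NA` means the
#'   regression default `ceiling(p / 3)` resolved at fit time.
#' @slot respFrac proportion of response variables scored at each split
#'   (redrawn per node); 1 scores all of them.
#' @slot nodesize minimum number of (in-bag) samples in a terminal node.
#' @slot maxDepth optional depth cap; `NA` means unlimited.
#' @slot nsplit number of random cut points per candidate predictor;
#'   0 means exhaustive search over all midpoints.
#' @slot seed integer seed; per-tree streams are derived from it so the
#'   forest is independent of execution order and of R's RNG state.
#' @exportClass ForestParams
setClass("ForestParams",
  representation(
    ntree = "integer", mtry = "integer", respFrac = "numeric",
    nodesize = "integer", maxDepth = "integer", nsplit = "integer",
    seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (object@ntree < 1L) msg <- c(msg, "ntree must be >= 1")
    if (object@nodesize < 1L) msg <- c(msg, "nodesize must be >= 1")
    if (!is.na(object@mtry) && object@mtry < 1L) {
      msg <- c(msg, "mtry must be >= 1")
    }
    if (object@respFrac <= 0 || object@respFrac > 1) {
      msg <- c(msg, "respFrac must be in (0, 1]")
    }
    if (object@nsplit < 0L) msg <- c(msg, "nsplit must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Create forest parameters
#'
#' @param ntree number of trees (default 100).
#' @param mtry candidate predictors per split; default `NA` resolves to
#'   `ceiling(p / 3)` when the forest is fitted.
#' @param respFrac proportion of responses scored per split (default 1).
#' @param nodesize minimum terminal node size (default 5).
#' @param maxDepth optional cap on tree depth (default `NA`, none).
#' @param nsplit random cut points per candidate (default 0 = exhaustive).
#' @param seed integer seed.
#' @return a [ForestParams-class] object.
#' @examples
#' forestParams(ntree = 50, seed = 7)
#' @export
forestParams <- function(ntree = 100L, mtry = NA_integer_, respFrac = 1,
                         nodesize = 5L, maxDepth = NA_integer_, nsplit = 0L,
                         seed = 1L) {
  new("ForestParams",
    ntree = as.integer(ntree), mtry = as.integer(mtry),
    respFrac = as.numeric(respFrac), nodesize = as.integer(nodesize),
    maxDepth = as.integer(maxDepth), nsplit = as.integer(nsplit),
    seed = as.integer(seed)
  )
}

# ---------------------------------------------------------------- forest ----

#' Multivariate random forest model
#'
#' A grown forest over a predictor matrix X (n x p) and a response matrix
#' Y (n x q). Each tree stores its bootstrap in-bag counts and a flat node
#' table: depth, split predictor, cut value, the maximal splitting response
#' variable (MSRV) of the split, the summed split criterion, and child ids.
#'
#' @slot trees list of per-tree node tables (one list per tree).
#' @slot params the [ForestParams-class] used.
#' @slot mtryUsed the resolved mtry.
#' @slot n,p,q sample, predictor, and response counts.
#' @slot predictorIds,responseIds feature identifiers of both sides.
#' @exportClass MrfForest
setClass("MrfForest",
  representation(
    trees = "list", params = "ForestParams", mtryUsed = "integer",
    n = "integer", p = "integer", q = "integer",
    predictorIds = "character", responseIds = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@trees) != object@params@ntree) {
      msg <- c(msg, "number of trees must equal params ntree")
    }
    if (length(object@predictorIds) != object@p) {
      msg <- c(msg, "predictorIds length must equal p")
    }
    if (length(object@responseIds) != object@q) {
      msg <- c(msg, "responseIds length must equal q")
    }
    if (length(msg)) msg else TRUE
  }
)

# ------------------------------------------------------------- profiles ----

#' Inverse minimal depth profile
#'
#' Per-variable inverse minimal depth (IMD) statistics for one side of a
#' forest (predictors or responses). The per-tree IMD of a variable is
#' 1/(minimal depth + 1) in trees where it appears and exactly 0 otherwise;
#' the forest IMD averages over all trees (zeros included).
#'
#' @slot side `"predictor"` or `"response"`.
#' @slot featureIds variable identifiers.
#' @slot perTreeImd B x nvars matrix of per-tree IMD values in [0, 1].
#' @slot forestImd per-variable mean over trees.
#' @slot se per-variable standard error of the mean across trees.
#' @slot tscore `(forestImd - mu) / se` (0 if both zero; +-Inf when se is 0
#'   and the IMD differs from mu).
#' @slot mu grand mean of forestImd over all variables of this side.
#' @exportClass ImdProfile
setClass("ImdProfile",
  representation(
    side = "character", featureIds = "character", perTreeImd = "matrix",
    forestImd = "numeric", se = "numeric", tscore = "numeric", mu = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (!object@side %in% c("predictor", "response")) {
      msg <- c(msg, "side must be 'predictor' or 'response'")
    }
    if (ncol(object@perTreeImd) != length(object@featureIds)) {
      msg <- c(msg, "perTreeImd columns must match featureIds")
    }
    if (any(object@perTreeImd < 0 | object@perTreeImd > 1)) {
      msg <- c(msg, "per-tree IMD values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  }
)

# ------------------------------------------------------------------ oob ----

#' Out-of-bag error report
#'
#' @slot perResponseErr per-response OOB mean squared error (length q).
#' @slot perPredictorErr per-predictor OOB mean squared error from the
#'   forest-weights predictor (length p).
#' @slot meanErr mean over the concatenated p + q errors.
#' @slot nCovered number of samples with at least one OOB tree.
#' @exportClass OobReport
setClass("OobReport",
  representation(
    perResponseErr = "numeric", perPredictorErr = "numeric",
    meanErr = "numeric", nCovered = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (any(object@perResponseErr < 0) || any(object@perPredictorErr < 0)) {
      msg <- c(msg, "OOB errors must be nonnegative")
    }
    m <- mean(c(object@perResponseErr, object@perPredictorErr))
    if (!isTRUE(all.equal(m, object@meanErr))) {
      msg <- c(msg, "meanErr must equal the mean of the concatenated errors")
    }
    if (length(msg)) msg else TRUE
  }
)

# -------------------------------------------------------------- mixture ----

#' Zero-inflated two-component mixture fit
#'
#' EM fit of a point mass at zero plus a two-component Gaussian (or
#' zero-truncated first component) mixture over positive IMD values.
#' Component 1 is the lower-mean (noise) component by construction.
#'
#' @slot modelKind `"gaussian"` or `"truncated_normal"`.
#' @slot p0 proportion of exact zeros.
#' @slot p weight of component 1 among nonzero values.
#' @slot mu1,sigma1,mu2,sigma2 component parameters.
#' @slot loglik final modified log-likelihood.
#' @slot loglikTrace per-iteration log-likelihood (non-decreasing).
#' @slot nIter iterations used.
#' @slot converged convergence flag.
#' @exportClass MixtureFit
setClass("MixtureFit",
  representation(
    modelKind = "character", p0 = "numeric", p = "numeric",
    mu1 = "numeric", sigma1 = "numeric", mu2 = "numeric", sigma2 = "numeric",
    loglik = "numeric", loglikTrace = "numeric", nIter = "integer",
    converged = "logical"
  ),
  validity = function(object) {
    msg <- character()
    if (object@p0 < 0 || object@p0 > 1) msg <- c(msg, "p0 must be in [0, 1]")
    if (object@p < 0 || object@p > 1) msg <- c(msg, "p must be in [0, 1]")
    if (object@sigma1 <= 0 || object@sigma2 <= 0) {
      msg <- c(msg, "component sds must be positive")
    }
    if (length(msg)) msg else TRUE
  }
)

# ------------------------------------------------------------ selection ----

#' Variable selection result
#'
#' @slot method `"filter"`, `"mixture"`, or `"transformation"`.
#' @slot side `"predictor"`, `"response"`, or a dataset tag for aggregated
#'   multi-omics selections.
#' @slot selectedIds selected variable identifiers.
#' @slot threshold the operative threshold(s): tau for the filter, pr for
#'   the mixture, the t-quantile for the transformation.
#' @slot diagnostics method-specific extras (OOB tuning curve, mixture fit,
#'   or t-scores).
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(
    method = "character", side = "character", selectedIds = "character",
    threshold = "numeric", diagnostics = "list"
  ),
  validity = function(object) {
    if (!object@method %in% c("filter", "mixture", "transformation")) {
      "method must be filter, mixture, or transformation"
    } else {
      TRUE
    }
  }
)

# ------------------------------------------------------------ scenarios ----

#' Latent-model simulation scenario
#'
#' Two or three omics matrices are generated from a shared latent draw
#' u ~ N(0, sigmaU^2) as `X(m) = g_m(u) w_m' + eps_m`: only the first
#' `pc[m]` entries of the unit-energy weight vector `w_m` are nonzero, so
#' those columns carry the cross-correlated signal.
#'
#' @slot n sample count.
#' @slot p per-dataset feature counts.
#' @slot pc per-dataset cross-correlated counts (0 allowed: pure noise).
#' @slot sigmaU latent standard deviation.
#' @slot noiseSd noise standard deviation (diagonal of the noise
#'   covariance); 0 gives the noiseless degenerate model.
#' @slot kernels per-dataset kernel tags among `"square"`, `"exp"`,
#'   `"identity"`.
#' @slot seed integer seed.
#' @exportClass LatentScenario
setClass("LatentScenario",
  representation(
    n = "integer", p = "integer", pc = "integer", sigmaU = "numeric",
    noiseSd = "numeric", kernels = "character", seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    m <- length(object@p)
    if (m < 2L || m > 3L) msg <- c(msg, "need 2 or 3 datasets")
    if (length(object@pc) != m || length(object@kernels) != m) {
      msg <- c(msg, "p, pc, kernels must have the same length")
    }
    if (any(object@pc > object@p) || any(object@pc < 0L)) {
      msg <- c(msg, "pc must satisfy 0 <= pc <= p")
    }
    if (object@sigmaU <= 0) msg <- c(msg, "sigmaU must be positive")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
    if (!all(object@kernels %in% c("square", "exp", "identity"))) {
      msg <- c(msg, "kernels must be among square, exp, identity")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Non-linear regression simulation scenario
#'
#' Predictor groups are noisy copies of shared basis variables and each
#' response combines an exponential and a logistic kernel of two bases.
#'
#' @slot n sample count.
#' @slot p2c number of cross-correlated response variables.
#' @slot g group size of each correlated predictor group.
#' @slot pd1,pd2 independent standard-normal noise columns appended to the
#'   predictor and response sides.
#' @slot basisIndexing `"pairs"` (default: response k uses bases 2k-1, 2k)
#'   or `"stride3"` (the literal 3k-2, 3k-1 indexing).
#' @slot seed integer seed.
#' @exportClass NonlinearScenario
setClass("NonlinearScenario",
  representation(
    n = "integer", p2c = "integer", g = "integer", pd1 = "integer",
    pd2 = "integer", basisIndexing = "character", seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (object@g < 1L) msg <- c(msg, "g must be >= 1")
    if (object@p2c < 1L) msg <- c(msg, "p2c must be >= 1")
    if (object@pd1 < 0L || object@pd2 < 0L) {
      msg <- c(msg, "pd1 and pd2 must be nonnegative")
    }
    if (!object@basisIndexing %in% c("pairs", "stride3")) {
      msg <- c(msg, "basisIndexing must be 'pairs' or 'stride3'")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Simulated multi-omics data with known truth
#'
#' @slot datasets named list of samples x features numeric matrices, each
#'   column standardized to mean 0, sd 1 (degenerate constant columns stay
#'   at 0).
#' @slot truth named list of per-dataset logical masks marking the
#'   cross-correlated (true) variables.
#' @exportClass SimulatedData
setClass("SimulatedData",
  representation(datasets = "list", truth = "list"),
  validity = function(object) {
    msg <- character()
    if (!identical(names(object@datasets), names(object@truth))) {
      msg <- c(msg, "datasets and truth must share names")
    }
    for (tag in names(object@datasets)) {
      if (ncol(object@datasets[[tag]]) != length(object@truth[[tag]])) {
        msg <- c(msg, sprintf("truth mask length mismatch for '%s'", tag))
      }
    }
    if (length(msg)) msg else TRUE
  }
)

# ----------------------------------------------------------- multiomics ----

#' A directional response <- predictor model between two omics layers
#'
#' @slot responseTag,predictorTag dataset tags (distinct).
#' @slot meanOob mean OOB error of the reduced ranking fit.
#' @slot forest the full-feature refit [MrfForest-class].
#' @exportClass DirectionModel
setClass("DirectionModel",
  representation(
    responseTag = "character", predictorTag = "character",
    meanOob = "numeric", forest = "MrfForest"
  ),
  validity = function(object) {
    if (identical(object@responseTag, object@predictorTag)) {
      "responseTag and predictorTag must differ"
    } else {
      TRUE
    }
  }
)

#' Multi-omics integration result
#'
#' @slot models the chosen model collection (one model per response
#'   dataset).
#' @slot meanImd named list of per-dataset aggregated mean-IMD vectors.
#' @slot selections named list of per-dataset [SelectionResult-class].
#' @exportClass IntegrationResult
setClass("IntegrationResult",
  representation(models = "list", meanImd = "list", selections = "list"),
  validity = function(object) {
    tags <- vapply(object@models, function(m) m@responseTag, character(1))
    if (anyDuplicated(tags)) {
      "each dataset must appear as response in exactly one model"
    } else {
      TRUE
    }
  }
)
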