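#' @include AllClasses.R
NULL

#' Normalize a weight vector to unit energy
#'
#' Divides each entry by the root sum of squares so the squared entries sum
#' to 1. Zero entries stay exactly zero.
#'
#' @param w0 raw numeric weight vector with at least one nonzero entry.
#' @return the rescaled vector.
#' @examples
#' normalizeWeights(c(3, 4, 0)) # 0.6 0.8 0.0
#' @export
normalizeWeights <- function(w0) {
  stopifnot(is.numeric(w0), length(w0) >= 1L)
  energy <- sum(w0^2)
  if (energy == 0) {
    stop("degenerate weights: all entries are zero")
  }
  w0 / sqrt(energy)
}

# standardize columns to mean 0, sd 1; constant columns are centered only
standardizeColumns <- function(M) {
  mu <- colMeans(M)
  M <- sweep(M, 2L, mu, "-")
  s <- sqrt(colSums(M^2) / (nrow(M) - 1L))
  keep <- s > 0
  M[, keep] <- sweep(M[, keep, drop = FALSE], 2L, s[keep], "/")
  M
}

#' Construct a latent-model scenario
#'
#' @param n sample count.
#' @param p integer vector of per-dataset feature counts (2 or 3 datasets).
#' @param pc integer vector of per-dataset cross-correlated counts.
#' @param sigmaU latent standard deviation (default 2).
#' @param noiseSd noise standard deviation (default 0.3).
#' @param kernels per-dataset kernel tags among `"square"`, `"exp"`,
#'   `"identity"`; defaults to `c("square", "exp")` for two datasets and
#'   adds `"identity"` for three.
#' @param seed integer seed.
#' @return a [LatentScenario-class].
#' @examples
#' latentScenario(n = 100, p = c(200, 200), pc = c(20, 20), seed = 1)
#' @export
latentScenario <- function(n, p, pc, sigmaU = 2, noiseSd = 0.3,
                           kernels = NULL, seed = 1L) {
  if (is.null(kernels)) {
    kernels <- c("square", "exp", "identity")[seq_along(p)]
  }
  new("LatentScenario",
    n = as.integer(n), p = as.integer(p), pc = as.integer(pc),
    sigmaU = as.numeric(sigmaU), noiseSd = as.numeric(noiseSd),
    kernels = as.character(kernels), seed = as.integer(seed)
  )
}

#' Construct a non-linear regression scenario
#'
#' Derived quantities: `pl = 2 * p2c` basis variables form the responses,
#' and `g * pl` cross-correlated predictor columns are generated.
#'
#' @param n sample count.
#' @param p2c number of cross-correlated responses.
#' @param g group size of each correlated predictor group.
#' @param pd1,pd2 independent noise columns for the predictor and response
#'   sides (default 0).
#' @param basisIndexing `"pairs"` (default) or `"stride3"`; see
#'   [NonlinearScenario-class].
#' @param seed integer seed.
#' @return a [NonlinearScenario-class].
#' @export
nonlinearScenario <- function(n, p2c, g, pd1 = 0L, pd2 = 0L,
                              basisIndexing = "pairs", seed = 1L) {
  new("NonlinearScenario",
    n = as.integer(n), p2c = as.integer(p2c), g = as.integer(g),
    pd1 = as.integer(pd1), pd2 = as.integer(pd2),
    basisIndexing = as.character(basisIndexing), seed = as.integer(seed)
  )
}

latentKernel <- function(tag) {
  switch(tag,
    square = function(u) u^2,
    exp = function(u) exp(u),
    identity = function(u) u,
    stop("unknown kernel tag: ", tag)
  )
}

#' Simulate latent-model multi-omics data
#'
#' Draws one latent vector u ~ N(0, sigmaU^2) shared by all datasets, then
#' generates each dataset as `g_m(u) w_m' + eps_m` where only the first
#' `pc[m]` weight entries are nonzero (U(-1, 1), normalized to unit energy)
#' and the noise is i.i.d. N(0, noiseSd^2). Every column is standardized to
#' mean 0, sd 1. The truth mask marks the first `pc[m]` columns.
#'
#' @param scn a [LatentScenario-class].
#' @return a [SimulatedData-class].
#' @examples
#' sim <- simulateLatent(latentScenario(50, c(40, 40), c(5, 5), seed = 3))
#' sapply(datasets(sim), dim)
#' @export
simulateLatent <- function(scn) {
  stopifnot(is(scn, "LatentScenario"))
  validObject(scn)
  set.seed(scn@seed)
  n <- scn@n
  u <- rnorm(n, 0, scn@sigmaU)
  dsets <- list()
  truth <- list()
  for (m in seq_along(scn@p)) {
    p <- scn@p[m]
    pc <- scn@pc[m]
    g <- latentKernel(scn@kernels[m])
    w <- numeric(p)
    if (pc > 0L) {
      w[seq_len(pc)] <- runif(pc, -1, 1)
      w <- normalizeWeights(w)
    }
    eps <- matrix(rnorm(n * p, 0, scn@noiseSd), n, p)
    X <- tcrossprod(g(u), w) + eps
    X <- standardizeColumns(X)
    tag <- paste0("omics", m)
    dimnames(X) <- list(
      paste0("S", seq_len(n)),
      paste0(tag, ".V", seq_len(p))
    )
    dsets[[tag]] <- X
    truth[[tag]] <- setNames(
      seq_len(p) <= pc,
      colnames(X)
    )
  }
  new("SimulatedData", datasets = dsets, truth = truth)
}

#' Simulate non-linear regression two-omics data
#'
#' Basis variables U are i.i.d. standard normal. Predictor group i consists
#' of g noisy copies of U_i: copy j has noise scale
#' `0.01 + 0.5 (j - 1) / (g - 1)` (plain unit noise for g = 1). Response k
#' combines an exponential and a logistic kernel of its two basis
#' variables: `0.25 exp(4 u_a) + 4 / (1 + exp(-20 u_b)) - 0.5`. Independent
#' standard-normal noise columns are appended to both sides and all columns
#' are standardized.
#'
#' @param scn a [NonlinearScenario-class].
#' @return a [SimulatedData-class]; dataset `"omics1"` holds the grouped
#'   predictors, `"omics2"` the responses.
#' @export
simulateNonlinear <- function(scn) {
  stopifnot(is(scn, "NonlinearScenario"))
  validObject(scn)
  set.seed(scn@seed)
  n <- scn@n
  p2c <- scn@p2c
  g <- scn@g
  pl <- 2L * p2c
  nb <- if (scn@basisIndexing == "pairs") pl else 3L * p2c - 1L
  U <- matrix(rnorm(n * nb), n, nb)

  # grouped predictors: group-major column order
  p1c <- g * pl
  X <- matrix(0, n, p1c)
  for (i in seq_len(pl)) {
    for (j in seq_len(g)) {
      scale <- if (g > 1L) 0.01 + 0.5 * (j - 1) / (g - 1) else 1
      X[, (i - 1L) * g + j] <- U[, i] + scale * rnorm(n)
    }
  }
  if (scn@pd1 > 0L) {
    X <- cbind(X, matrix(rnorm(n * scn@pd1), n, scn@pd1))
  }

  Y <- matrix(0, n, p2c)
  for (k in seq_len(p2c)) {
    if (scn@basisIndexing == "pairs") {
      ua <- U[, 2L * k - 1L]
      ub <- U[, 2L * k]
    } else {
      ua <- U[, 3L * k - 2L]
      ub <- U[, 3L * k - 1L]
    }
    Y[, k] <- 0.25 * exp(4 * ua) + 4 / (1 + exp(-20 * ub)) - 0.5
  }
  if (scn@pd2 > 0L) {
    Y <- cbind(Y, matrix(rnorm(n * scn@pd2), n, scn@pd2))
  }

  X <- standardizeColumns(X)
  Y <- standardizeColumns(Y)
  dimnames(X) <- list(paste0("S", seq_len(n)),
                      paste0("omics1.V", seq_len(ncol(X))))
  dimnames(Y) <- list(paste0("S", seq_len(n)),
                      paste0("omics2.V", seq_len(ncol(Y))))

  new("SimulatedData",
    datasets = list(omics1 = X, omics2 = Y),
    truth = list(
      omics1 = setNames(seq_len(ncol(X)) <= p1c, colnames(X)),
      omics2 = setNames(seq_len(ncol(Y)) <= p2c, colnames(Y))
    )
  )
}

#' Simulate data from any scenario
#'
#' Dispatches to [simulateLatent()] or [simulateNonlinear()].
#'
#' @param scn a scenario object.
#' @return a [SimulatedData-class].
#' @export
simulateData <- function(scn) {
  if (is(scn, "LatentScenario")) {
    simulateLatent(scn)
  } else if (is(scn, "NonlinearScenario")) {
    simulateNonlinear(scn)
  } else {
    stop("unknown scenario class: ", class(scn)[1])
  }
}
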