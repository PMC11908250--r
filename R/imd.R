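#' @include forest.R
NULL

#' Minimal depths of variables in one tree
#'
#' The minimal depth of a variable is the shallowest depth at which it
#' appears in the tree: as a split variable for predictors, as the MSRV of
#' a split for responses. Variables never appearing are absent from the
#' returned map.
#'
#' @param forest an [MrfForest-class].
#' @param treeIndex which tree (1-based).
#' @param side `"predictor"` or `"response"`.
#' @return named integer vector of minimal depths (names are variable
#'   indices as characters); possibly empty.
#' @export
treeMinimalDepths <- function(forest, treeIndex,
                              side = c("predictor", "response")) {
  side <- match.arg(side)
  tr <- forest@trees[[treeIndex]]
  internal <- !is.na(tr$splitVar)
  if (!any(internal)) {
    return(setNames(integer(0), character(0)))
  }
  vars <- if (side == "predictor") tr$splitVar[internal] else tr$msrv[internal]
  depths <- tr$depth[internal]
  md <- tapply(depths, vars, min)
  setNames(as.integer(md), names(md))
}

#' Inverse minimal depth
#'
#' `1 / (depth + 1)` for a variable appearing at minimal depth `depth`;
#' exactly 0 for a variable absent from the tree (encoded as `NA`). Larger
#' values mean stronger variables, and the statistic is confined to
#' [0, 1] regardless of tree size.
#'
#' @param depth integer vector of minimal depths; `NA` = absent.
#' @return numeric vector in [0, 1].
#' @examples
#' inverseMinimalDepth(c(0, 1, NA)) # 1, 0.5, 0
#' @export
inverseMinimalDepth <- function(depth) {
  if (any(depth < 0, na.rm = TRUE)) stop("minimal depth cannot be negative")
  out <- 1 / (depth + 1)
  out[is.na(depth)] <- 0
  out
}

# per-tree IMD matrix (B x nvars) for one side
perTreeImdMatrix <- function(forest, side, nvars) {
  B <- length(forest@trees)
  M <- matrix(0, B, nvars)
  for (b in seq_len(B)) {
    md <- treeMinimalDepths(forest, b, side)
    if (length(md)) {
      M[b, as.integer(names(md))] <- 1 / (md + 1)
    }
  }
  M
}

# assemble an ImdProfile from a per-tree IMD matrix
profileFromMatrix <- function(M, side, ids) {
  B <- nrow(M)
  fi <- colMeans(M)
  if (B > 1L) {
    v <- (colMeans(M^2) - fi^2) * B / (B - 1L)
    v[v < 0] <- 0
    se <- sqrt(v) / sqrt(B)
  } else {
    se <- rep(NA_real_, ncol(M))
  }
  mu <- mean(fi)
  tsc <- (fi - mu) / se
  zero <- !is.na(se) & se == 0
  tsc[zero & fi == mu] <- 0
  tsc[zero & fi > mu] <- Inf
  tsc[zero & fi < mu] <- -Inf
  new("ImdProfile",
    side = side, featureIds = ids, perTreeImd = M,
    forestImd = unname(fi), se = unname(se), tscore = unname(tsc), mu = mu
  )
}

#' Forest IMD profiles for predictors and responses
#'
#' Assembles the per-tree IMD matrix of every variable (0 in trees where
#' the variable does not appear), the forest IMD (mean over all trees,
#' zeros included), the standard error of that mean across trees, and the
#' t-score `(forestImd - mu) / se` where mu is the grand mean of the
#' forest IMD over all variables of the same side. Predictor-side and
#' response-side profiles are never pooled.
#'
#' @param forest an [MrfForest-class].
#' @return list with elements `predictor` and `response`, each an
#'   [ImdProfile-class].
#' @examples
#' sim <- simulateLatent(latentScenario(60, c(30, 30), c(5, 5), seed = 1))
#' fit <- mrfForest(datasets(sim)$omics1, datasets(sim)$omics2,
#'                  forestParams(ntree = 20, seed = 1))
#' prof <- imdProfiles(fit)
#' head(forestImd(prof$predictor))
#' @export
imdProfiles <- function(forest) {
  list(
    predictor = profileFromMatrix(
      perTreeImdMatrix(forest, "predictor", forest@p),
      "predictor", forest@predictorIds
    ),
    response = profileFromMatrix(
      perTreeImdMatrix(forest, "response", forest@q),
      "response", forest@responseIds
    )
  )
}

#' Null minimal-depth distribution of a weak variable
#'
#' Probability that a weak (noise) variable attains minimal depth d in a
#' balanced tree with p features:
#' `(1 - 1/p)^(2^d - 1) * (1 - (1 - 1/p)^(2^d))`. In high dimension these
#' probabilities all collapse toward 0, which is why thresholds derived
#' from them fail there.
#'
#' @param p number of features (>= 1).
#' @param d depth (vectorized, >= 0).
#' @return probability vector.
#' @examples
#' weakMdPmf(2, 0) # 0.5
#' @export
weakMdPmf <- function(p, d) {
  stopifnot(p >= 1, all(d >= 0))
  Ld <- 2^d - 1
  ell <- 2^d
  (1 - 1 / p)^Ld * (1 - (1 - 1 / p)^ell)
}

#' General minimal-depth distribution
#'
#' `P(Dv = d) = prod_{j < d} (1 - pi_j theta_j)^{ell_j} *
#' (1 - (1 - pi_d theta_d)^{ell_d})` where `piTheta[j + 1]` is the product
#' of the candidate-selection and split probabilities of the variable at
#' depth j and `ell[j + 1]` the number of nodes at depth j. The IMD
#' distribution is the same law under the change of variable
#' `d = 1 / dI - 1` (see [imdPmf()]).
#'
#' @param piTheta per-depth selection x split probabilities (depth 0, 1, ...).
#' @param ell per-depth node counts (2^d for a balanced tree).
#' @param d depth at which to evaluate (scalar).
#' @return the probability.
#' @export
mdPmf <- function(piTheta, ell, d) {
  stopifnot(
    all(piTheta >= 0 & piTheta <= 1), all(ell > 0),
    d >= 0, d < length(piTheta)
  )
  before <- if (d > 0) {
    prod((1 - piTheta[seq_len(d)])^ell[seq_len(d)])
  } else {
    1
  }
  before * (1 - (1 - piTheta[d + 1])^ell[d + 1])
}

#' Minimal-depth distribution on the IMD scale
#'
#' Pure change of variable of [mdPmf()]: the probability that the IMD of a
#' selected variable equals `dI` is the probability that its minimal depth
#' equals `1 / dI - 1`.
#'
#' @inheritParams mdPmf
#' @param dI inverse minimal depth in (0, 1] with `1 / dI` integral.
#' @return the probability.
#' @export
imdPmf <- function(piTheta, ell, dI) {
  stopifnot(dI > 0, dI <= 1)
  d <- round(1 / dI - 1)
  mdPmf(piTheta, ell, d)
}
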