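#' @include imd.R oob.R
NULL

#' Variables kept by the standard-deviation filter at a given tau
#'
#' A variable passes the filter when its forest IMD exceeds
#' `tau * sd(forest IMD)` of its own side.
#'
#' @param profile an [ImdProfile-class].
#' @param tau nonnegative multiplier; `tau = 0` keeps every variable with
#'   strictly positive IMD.
#' @return character vector of kept variable ids.
#' @export
filterThreshold <- function(profile, tau) {
  stopifnot(tau >= 0)
  thr <- tau * sd(profile@forestImd)
  profile@featureIds[profile@forestImd > thr]
}

#' IMD filter selection with OOB-tuned tau
#'
#' For each tau on the grid, variables of both sides with forest IMD above
#' `tau * sd(IMD)` are kept and the forest is refitted on the kept
#' variables; the mean OOB error over all kept predictors and responses,
#' averaged over `kRepeats` refits with fresh derived seeds, scores the
#' threshold. The chosen tau is the largest one whose mean error is within
#' one standard deviation (across repeats) of the grid minimum, favouring
#' the sparser model. Grid points where either side empties out are
#' skipped with a warning.
#'
#' @param forest the base [MrfForest-class] grown on (X, Y).
#' @param X,Y the training matrices.
#' @param tauGrid ascending tau grid (default `seq(0.1, 3, by = 0.1)`).
#' @param kRepeats refits per tau (default 5).
#' @param refitNtree tree count of the tuning refits (default 100). The
#'   refits only feed the mean OOB error — an average over all p + q
#'   variables that is already stable at moderate tree counts and further
#'   averaged over `kRepeats` — so they need not match the (possibly much
#'   larger) base forest.
#' @return list with elements `predictor` and `response`, each a
#'   [SelectionResult-class]; the shared tuning curve is in the
#'   diagnostics of both.
#' @export
selectFilter <- function(forest, X, Y, tauGrid = seq(0.1, 3, by = 0.1),
                         kRepeats = 5L, refitNtree = 100L) {
  stopifnot(kRepeats >= 1L, !is.unsorted(tauGrid))
  prof <- imdProfiles(forest)
  params <- forest@params

  keptAt <- lapply(tauGrid, function(tau) {
    list(
      p = which(prof$predictor@forestImd > tau * sd(prof$predictor@forestImd)),
      q = which(prof$response@forestImd > tau * sd(prof$response@forestImd))
    )
  })

  # identical kept sets share one refit per repeat
  cache <- new.env(parent = emptyenv())
  refitErr <- function(keep, r) {
    key <- paste(c("P", keep$p, "Q", keep$q, "r", r), collapse = ",")
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    pr <- params
    pr@seed <- deriveSeed(params@seed, r, length(keep$p), length(keep$q))
    pr@mtry <- NA_integer_
    pr@ntree <- as.integer(refitNtree)
    Xk <- X[, keep$p, drop = FALSE]
    Yk <- Y[, keep$q, drop = FALSE]
    fit <- mrfForest(Xk, Yk, pr)
    err <- reducedModelMeanOob(fit, Xk, Yk, X, Y, keep$p, keep$q)
    cache[[key]] <- err
    err
  }

  meanErr <- sdErr <- rep(NA_real_, length(tauGrid))
  for (i in seq_along(tauGrid)) {
    keep <- keptAt[[i]]
    if (length(keep$p) == 0L || length(keep$q) == 0L) {
      warning(sprintf(
        "tau = %.1f leaves an empty side; skipped", tauGrid[i]
      ))
      next
    }
    errs <- vapply(seq_len(kRepeats), function(r) refitErr(keep, r),
                   numeric(1))
    meanErr[i] <- mean(errs)
    sdErr[i] <- if (kRepeats > 1L) sd(errs) else 0
  }

  ok <- which(!is.na(meanErr))
  if (length(ok) == 0L) stop("no tau on the grid kept a non-empty model")
  iMin <- ok[which.min(meanErr[ok])]
  tol <- meanErr[iMin] + sdErr[iMin]
  iChosen <- max(ok[meanErr[ok] <= tol])
  tauStar <- tauGrid[iChosen]

  curve <- data.frame(
    tau = tauGrid, meanOob = meanErr, sdOob = sdErr,
    sizePredictor = vapply(keptAt, function(k) length(k$p), integer(1)),
    sizeResponse = vapply(keptAt, function(k) length(k$q), integer(1))
  )
  mk <- function(side, ids) {
    new("SelectionResult",
      method = "filter", side = side, selectedIds = ids,
      threshold = c(tau = tauStar),
      diagnostics = list(oobCurve = curve, tauMin = tauGrid[iMin])
    )
  }
  list(
    predictor = mk("predictor", forest@predictorIds[keptAt[[iChosen]]$p]),
    response = mk("response", forest@responseIds[keptAt[[iChosen]]$q])
  )
}

# Mean OOB error of a reduced refit, scored over ALL original variables:
# kept columns get their honest forest OOB error, dropped columns the
# error of the null (column-mean) prediction. Dropping a noise column
# therefore costs nothing while dropping a predictable one raises the
# average, which is what makes the tau tuning curve turn upward once
# signal variables start falling out of the model.
reducedModelMeanOob <- function(fit, Xk, Yk, X, Y, keepP, keepQ) {
  nullErr <- function(M) {
    ctr <- sweep(M, 2L, colMeans(M), "-")
    colMeans(ctr^2)
  }
  errR <- rep(NA_real_, ncol(Y))
  errR[keepQ] <- responseOobError(fit, Xk, Yk)
  if (length(keepQ) < ncol(Y)) {
    errR[-keepQ] <- nullErr(Y[, -keepQ, drop = FALSE])
  }
  errP <- rep(NA_real_, ncol(X))
  errP[keepP] <- predictorOobError(fit, Xk)
  if (length(keepP) < ncol(X)) {
    errP[-keepP] <- nullErr(X[, -keepP, drop = FALSE])
  }
  mean(c(errR, errP))
}

# ---------------------------------------------------------------- mixture ----

mixtureDensity <- function(x, mu, sigma, kind, component) {
  d <- dnorm(x, mu, sigma)
  if (kind == "truncated_normal" && component == 1L) {
    # zero-truncated first (noise) component
    d <- d / (1 - pnorm(0, mu, sigma))
  }
  d
}

# observed-data modified log-likelihood of the zero-inflated mixture
zimLoglik <- function(xs, n0, p0, p, mu1, s1, mu2, s2, kind) {
  p1 <- p * (1 - p0)
  p2 <- (1 - p) * (1 - p0)
  ll0 <- if (n0 > 0) n0 * log(p0) else 0
  dens <- p1 * mixtureDensity(xs, mu1, s1, kind, 1L) +
    p2 * mixtureDensity(xs, mu2, s2, kind, 2L)
  ll0 + sum(log(pmax(dens, .Machine$double.xmin)))
}

#' Fit a zero-inflated two-component mixture to forest IMD values
#'
#' The point mass at zero gets the exact empirical zero fraction `p0`; the
#' positive values are fitted by EM with a two-component Gaussian mixture
#' (default) or a variant whose first component is a zero-truncated
#' normal. Components are labelled so that component 1 has the smaller
#' mean (the noise component). Initialization splits the nonzero values
#' at their 75th percentile (fixed, seed-free).
#'
#' @param x numeric IMD values in [0, 1].
#' @param modelKind `"gaussian"` or `"truncated_normal"`.
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param maxIter maximum EM iterations (default 1000).
#' @return a [MixtureFit-class].
#' @examples
#' set.seed(1)
#' x <- c(numeric(30), rnorm(50, 0.05, 0.01), rnorm(20, 0.5, 0.05))
#' fitMixture(pmax(x, 0))
#' @export
fitMixture <- function(x, modelKind = c("gaussian", "truncated_normal"),
                       tol = 1e-6, maxIter = 1000L) {
  modelKind <- match.arg(modelKind)
  stopifnot(is.numeric(x), all(x >= 0 & x <= 1))
  n0 <- sum(x == 0)
  p0 <- n0 / length(x)
  xs <- x[x != 0]
  if (length(xs) < 10L) {
    stop("mixture unfittable: fewer than 10 nonzero IMD values")
  }

  # fixed quantile-split initialization
  cut <- quantile(xs, 0.75, names = FALSE)
  lo <- xs <= cut
  if (all(lo) || !any(lo)) lo <- xs <= stats::median(xs)
  if (all(lo) || !any(lo)) lo <- seq_along(xs) <= length(xs) / 2
  p <- mean(lo)
  mu1 <- mean(xs[lo])
  mu2 <- mean(xs[!lo])
  s1 <- max(sd(xs[lo]), 1e-4)
  s2 <- max(sd(xs[!lo]), 1e-4)
  if (is.na(s2)) s2 <- s1

  trace <- numeric(0)
  llOld <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    # E-step
    d1 <- p * mixtureDensity(xs, mu1, s1, modelKind, 1L)
    d2 <- (1 - p) * mixtureDensity(xs, mu2, s2, modelKind, 2L)
    tot <- pmax(d1 + d2, .Machine$double.xmin)
    g1 <- d1 / tot
    # M-step
    p <- min(max(mean(g1), 1e-8), 1 - 1e-8)
    w2 <- 1 - g1
    if (modelKind == "gaussian") {
      mu1 <- weighted.mean(xs, g1)
      s1 <- max(sqrt(weighted.mean((xs - mu1)^2, g1)), 1e-6)
    } else {
      # weighted truncated-normal MLE by direct maximization
      obj <- function(par) {
        m <- par[1]
        s <- exp(par[2])
        -sum(g1 * log(pmax(
          mixtureDensity(xs, m, s, modelKind, 1L), .Machine$double.xmin
        )))
      }
      opt <- optim(c(mu1, log(s1)), obj, method = "Nelder-Mead",
                   control = list(maxit = 100))
      if (opt$value <= obj(c(mu1, log(s1)))) {
        mu1 <- opt$par[1]
        s1 <- max(exp(opt$par[2]), 1e-6)
      }
    }
    mu2 <- weighted.mean(xs, w2)
    s2 <- max(sqrt(weighted.mean((xs - mu2)^2, w2)), 1e-6)

    ll <- zimLoglik(xs, n0, p0, p, mu1, s1, mu2, s2, modelKind)
    trace <- c(trace, ll)
    if (is.finite(llOld) && abs(ll - llOld) < tol) {
      converged <- TRUE
      break
    }
    llOld <- ll
  }

  if (mu1 > mu2) {
    # enforce component 1 = smaller mean (noise)
    tmp <- c(mu1, s1)
    mu1 <- mu2
    s1 <- s2
    mu2 <- tmp[1]
    s2 <- tmp[2]
    p <- 1 - p
  }

  new("MixtureFit",
    modelKind = modelKind, p0 = p0, p = p,
    mu1 = mu1, sigma1 = s1, mu2 = mu2, sigma2 = s2,
    loglik = trace[length(trace)], loglikTrace = trace,
    nIter = iter, converged = converged
  )
}

#' Posterior component probabilities of a fitted mixture
#'
#' Component 0 is the zero mass: its posterior is 1 exactly at x = 0 and 0
#' elsewhere. For positive x the posteriors of components 1 and 2 are the
#' usual density ratios and the three columns sum to 1.
#'
#' @param fit a [MixtureFit-class].
#' @param x numeric values in [0, 1].
#' @return matrix with columns `Pr0`, `Pr1`, `Pr2`.
#' @export
posteriorProbs <- function(fit, x) {
  stopifnot(is(fit, "MixtureFit"))
  out <- matrix(0, length(x), 3L,
                dimnames = list(NULL, c("Pr0", "Pr1", "Pr2")))
  zero <- x == 0
  out[zero, "Pr0"] <- 1
  if (any(!zero)) {
    xs <- x[!zero]
    # floor both densities so posteriors stay strictly inside (0, 1)
    d1 <- pmax(
      fit@p * mixtureDensity(xs, fit@mu1, fit@sigma1, fit@modelKind, 1L),
      1e-300
    )
    d2 <- pmax(
      (1 - fit@p) *
        mixtureDensity(xs, fit@mu2, fit@sigma2, fit@modelKind, 2L),
      1e-300
    )
    tot <- d1 + d2
    # posteriors of positive values are strictly inside (0, 1) in exact
    # arithmetic; keep them there under floating-point underflow too
    p1 <- pmin(pmax(d1 / tot, 1e-16), 1 - 1e-16)
    out[!zero, "Pr1"] <- p1
    out[!zero, "Pr2"] <- 1 - p1
  }
  out
}

#' Mixture-model selection
#'
#' Fits the zero-inflated mixture to the forest IMD of one side and
#' selects the variables whose posterior probability of the low-mean
#' (noise) component is below `pr`. Zero-IMD variables are never selected.
#'
#' @param profile an [ImdProfile-class].
#' @param pr posterior cutoff (default 0.05).
#' @param modelKind passed to [fitMixture()].
#' @return a [SelectionResult-class] with the fit in its diagnostics.
#' @export
selectMixture <- function(profile, pr = 0.05, modelKind = "gaussian") {
  fit <- fitMixture(profile@forestImd, modelKind = modelKind)
  post <- posteriorProbs(fit, profile@forestImd)
  keep <- profile@forestImd > 0 & post[, "Pr1"] < pr
  new("SelectionResult",
    method = "mixture", side = profile@side,
    selectedIds = profile@featureIds[keep],
    threshold = c(pr = pr),
    diagnostics = list(fit = fit, posterior = post)
  )
}

#' t-score IMD selection
#'
#' Selects variables whose t-score IMD exceeds the Student-t quantile with
#' `ntree - 1` degrees of freedom. The default `"upper"` tail uses the
#' magnitude of the 5% point, `qt(1 - alpha, B - 1)`, matching the
#' reported selection behaviour; `tail = "lower"` applies the literal
#' lower-tail cut `qt(alpha, B - 1)` instead.
#'
#' @param profile an [ImdProfile-class].
#' @param alpha tail level (default 0.05).
#' @param tail `"upper"` (default) or `"lower"`.
#' @return a [SelectionResult-class].
#' @export
selectTransformation <- function(profile, alpha = 0.05,
                                 tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  B <- nrow(profile@perTreeImd)
  if (B < 2L) stop("t-score selection needs at least 2 trees (df = B - 1)")
  Q <- if (tail == "upper") qt(1 - alpha, df = B - 1) else qt(alpha, df = B - 1)
  keep <- !is.na(profile@tscore) & profile@tscore > Q
  new("SelectionResult",
    method = "transformation", side = profile@side,
    selectedIds = profile@featureIds[keep],
    threshold = c(tQuantile = Q),
    diagnostics = list(alpha = alpha, df = B - 1, tail = tail,
                       tscore = setNames(profile@tscore, profile@featureIds))
  )
}
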