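#' @include selection.R
NULL

#' PCA dimension reduction for direction ranking
#'
#' Scores of the leading principal components whose cumulative explained
#' variance first reaches `varThreshold`. Used only to rank directional
#' models cheaply; final IMD profiles always come from full-feature fits.
#'
#' @param M standardized samples x features matrix.
#' @param varThreshold cumulative variance target in (0, 1] (default 0.8).
#' @return samples x components score matrix.
#' @export
pcaReduce <- function(M, varThreshold = 0.8) {
  stopifnot(varThreshold > 0, varThreshold <= 1)
  pr <- prcomp(M, center = TRUE, scale. = FALSE)
  v <- pr$sdev^2
  if (sum(v) == 0) stop("constant matrix cannot be reduced")
  k <- which(cumsum(v) / sum(v) >= varThreshold - 1e-12)[1]
  pr$x[, seq_len(k), drop = FALSE]
}

# unit-variance rescaling so mean OOB errors are comparable across
# directions (constant columns dropped)
scaleScores <- function(S) {
  s <- apply(S, 2L, sd)
  S <- S[, s > 0, drop = FALSE]
  sweep(S, 2L, s[s > 0], "/")
}

#' Choose optimal directional models between omics datasets
#'
#' Every ordered pair (response dataset i, predictor dataset j) is fitted
#' as a multivariate forest on PCA-reduced, unit-variance scores; for each
#' response dataset the predictor with the lowest mean OOB error wins.
#' The K winning directions are then refitted on the full feature
#' matrices, giving the model collection over which IMD profiles are
#' aggregated.
#'
#' @param dsets named list of K >= 2 samples x features matrices on
#'   identical samples.
#' @param params [ForestParams-class] for all fits.
#' @param varThreshold cumulative variance for [pcaReduce()] (default 0.8).
#' @return list of [DirectionModel-class], one per response dataset.
#' @export
chooseDirections <- function(dsets, params = forestParams(),
                             varThreshold = 0.8) {
  K <- length(dsets)
  stopifnot(K >= 2L, !is.null(names(dsets)))
  ns <- vapply(dsets, nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all datasets must share the same samples")
  }
  tags <- names(dsets)
  reduced <- lapply(dsets, function(M) scaleScores(pcaReduce(M, varThreshold)))

  models <- vector("list", K)
  for (i in seq_len(K)) {
    bestErr <- Inf
    bestJ <- NA_integer_
    for (j in seq_len(K)) {
      if (i == j) next
      pr <- params
      pr@seed <- deriveSeed(params@seed, i, j)
      fit <- mrfForest(reduced[[j]], reduced[[i]], pr)
      err <- meanOobError(oobReport(fit, reduced[[j]], reduced[[i]]))
      if (err < bestErr) {
        bestErr <- err
        bestJ <- j
      }
    }
    pr <- params
    pr@seed <- deriveSeed(params@seed, i, bestJ, 1L)
    full <- mrfForest(dsets[[bestJ]], dsets[[i]], pr)
    models[[i]] <- new("DirectionModel",
      responseTag = tags[i], predictorTag = tags[bestJ],
      meanOob = bestErr, forest = full
    )
  }
  models
}

# per-dataset list of forest-IMD vectors drawn from every model in which
# the dataset appears (response or predictor side)
collectImd <- function(models) {
  out <- list()
  add <- function(tag, v) {
    out[[tag]] <<- c(out[[tag]], list(v))
  }
  for (m in models) {
    prof <- imdProfiles(m@forest)
    add(m@predictorTag, forestImd(prof$predictor))
    add(m@responseTag, forestImd(prof$response))
  }
  out
}

meanImdProfiles <- function(models) {
  lapply(collectImd(models), function(lst) {
    Reduce(`+`, lst) / length(lst)
  })
}

#' Aggregate IMD over the model collection and select per dataset
#'
#' Filter and mixture rules act on each variable's mean forest IMD over
#' every model in which its dataset appears; for the filter, tau is tuned
#' by refitting every model of the collection on the kept variables and
#' averaging their mean OOB errors (one-standard-deviation rule, as in
#' the two-omics case). The transformation rule instead runs per-model
#' t-score selection and keeps the variables selected by a strict
#' majority of the models containing them.
#'
#' @param models list of [DirectionModel-class] (the collection).
#' @param dsets the named full feature matrices used to build the models.
#' @param method `"filter"`, `"mixture"`, or `"transformation"`.
#' @param tauGrid,kRepeats,refitNtree filter tuning controls (see
#'   [selectFilter()]).
#' @param pr mixture posterior cutoff.
#' @param alpha transformation tail level.
#' @return named list of per-dataset [SelectionResult-class].
#' @export
aggregateAndSelect <- function(models, dsets,
                               method = c("filter", "mixture",
                                          "transformation"),
                               tauGrid = seq(0.1, 3, by = 0.1),
                               kRepeats = 5L, pr = 0.05, alpha = 0.05,
                               refitNtree = 100L) {
  method <- match.arg(method)
  tags <- names(dsets)
  meanImd <- meanImdProfiles(models)

  if (method == "transformation") {
    votes <- list()
    total <- list()
    for (tag in tags) {
      votes[[tag]] <- setNames(numeric(ncol(dsets[[tag]])),
                               colnames(dsets[[tag]]))
      total[[tag]] <- votes[[tag]]
    }
    for (m in models) {
      prof <- imdProfiles(m@forest)
      for (side in c("predictor", "response")) {
        tag <- if (side == "predictor") m@predictorTag else m@responseTag
        sel <- selectTransformation(prof[[side]], alpha = alpha)
        votes[[tag]][selectedIds(sel)] <- votes[[tag]][selectedIds(sel)] + 1
        total[[tag]] <- total[[tag]] + 1
      }
    }
    out <- lapply(tags, function(tag) {
      keep <- total[[tag]] > 0 & votes[[tag]] > total[[tag]] / 2
      new("SelectionResult",
        method = "transformation", side = tag,
        selectedIds = names(votes[[tag]])[keep],
        threshold = c(alpha = alpha),
        diagnostics = list(votes = votes[[tag]], models = total[[tag]])
      )
    })
    names(out) <- tags
    return(out)
  }

  if (method == "mixture") {
    out <- lapply(tags, function(tag) {
      v <- meanImd[[tag]]
      fit <- fitMixture(v)
      post <- posteriorProbs(fit, v)
      keep <- v > 0 & post[, "Pr1"] < pr
      new("SelectionResult",
        method = "mixture", side = tag,
        selectedIds = names(v)[keep], threshold = c(pr = pr),
        diagnostics = list(fit = fit, meanImd = v)
      )
    })
    names(out) <- tags
    return(out)
  }

  # filter: threshold the mean-IMD profile, tune tau by refitting the
  # whole collection on the kept variables
  params <- models[[1]]@forest@params
  keptAt <- lapply(tauGrid, function(tau) {
    lapply(meanImd, function(v) which(v > tau * sd(v)))
  })
  cache <- new.env(parent = emptyenv())
  refitErr <- function(keep, r) {
    key <- paste(c(unlist(lapply(keep, paste, collapse = ".")), r),
                 collapse = "|")
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    errs <- vapply(models, function(m) {
      Xf <- dsets[[m@predictorTag]]
      Yf <- dsets[[m@responseTag]]
      kp <- keep[[m@predictorTag]]
      kq <- keep[[m@responseTag]]
      Xk <- Xf[, kp, drop = FALSE]
      Yk <- Yf[, kq, drop = FALSE]
      pm <- params
      pm@seed <- deriveSeed(params@seed, r, ncol(Xk), ncol(Yk))
      pm@mtry <- NA_integer_
      pm@ntree <- as.integer(refitNtree)
      fit <- mrfForest(Xk, Yk, pm)
      # score all original variables of both layers, as in selectFilter
      reducedModelMeanOob(fit, Xk, Yk, Xf, Yf, kp, kq)
    }, numeric(1))
    cache[[key]] <- mean(errs)
    cache[[key]]
  }
  meanErr <- sdErr <- rep(NA_real_, length(tauGrid))
  for (i in seq_along(tauGrid)) {
    keep <- keptAt[[i]]
    if (any(vapply(keep, length, integer(1)) == 0L)) {
      warning(sprintf("tau = %.1f leaves an empty dataset; skipped",
                      tauGrid[i]))
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
  iChosen <- max(ok[meanErr[ok] <= meanErr[iMin] + sdErr[iMin]])
  out <- lapply(tags, function(tag) {
    v <- meanImd[[tag]]
    new("SelectionResult",
      method = "filter", side = tag,
      selectedIds = names(v)[keptAt[[iChosen]][[tag]]],
      threshold = c(tau = tauGrid[iChosen]),
      diagnostics = list(
        oobCurve = data.frame(tau = tauGrid, meanOob = meanErr,
                              sdOob = sdErr),
        meanImd = v
      )
    )
  })
  names(out) <- tags
  out
}

#' End-to-end multi-omics integration
#'
#' Builds the directional model collection with [chooseDirections()], then
#' aggregates IMD profiles and selects variables per dataset with
#' [aggregateAndSelect()].
#'
#' @inheritParams chooseDirections
#' @inheritParams aggregateAndSelect
#' @return an [IntegrationResult-class].
#' @export
integrateOmics <- function(dsets, params = forestParams(),
                           method = "transformation", varThreshold = 0.8,
                           tauGrid = seq(0.1, 3, by = 0.1), kRepeats = 5L,
                           pr = 0.05, alpha = 0.05) {
  models <- chooseDirections(dsets, params, varThreshold)
  selections <- aggregateAndSelect(
    models, dsets, method,
    tauGrid = tauGrid, kRepeats = kRepeats, pr = pr, alpha = alpha
  )
  new("IntegrationResult",
    models = models, meanImd = meanImdProfiles(models),
    selections = selections
  )
}
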