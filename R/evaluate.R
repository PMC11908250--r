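#' @include multiomics.R simulate.R
NULL

#' Confusion counts and rates of a variable selection
#'
#' @param selected character vector of selected ids (or logical mask over
#'   the truth universe).
#' @param truth named logical truth mask over the variable universe.
#' @return list with `tp`, `fp`, `fn`, `recall`, `precision`; the
#'   precision of an empty selection is reported as 0 with attribute
#'   `"undefined" = TRUE`.
#' @examples
#' truth <- c(a = TRUE, b = TRUE, c = FALSE)
#' confusionAndRates(c("a", "c"), truth)
#' @export
confusionAndRates <- function(selected, truth) {
  stopifnot(is.logical(truth), !is.null(names(truth)))
  if (is.logical(selected)) selected <- names(truth)[selected]
  selected <- intersect(selected, names(truth))
  tp <- sum(truth[selected])
  fp <- length(selected) - tp
  fn <- sum(truth) - tp
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (length(selected) == 0L) {
    precision <- 0
    attr(precision, "undefined") <- TRUE
  } else {
    precision <- tp / (tp + fp)
  }
  list(tp = tp, fp = fp, fn = fn, recall = recall, precision = precision)
}

#' Area under the precision-recall curve
#'
#' Average precision over the score ranking (the step rule without
#' interpolation): the mean of precision-at-k over the positions of the
#' positives. Tied scores share a rank; the pessimistic ordering is used
#' (negatives before positives within a tie), so the value is a worst
#' case over tie resolutions. If all scores are equal the positive
#' prevalence is returned with a warning.
#'
#' @param scores per-variable ranking scores (higher = more important).
#' @param truth logical truth mask aligned with `scores`.
#' @return the average precision in [0, 1].
#' @examples
#' prAuc(c(0.9, 0.8, 0.7, 0.6, 0.5), c(TRUE, FALSE, TRUE, TRUE, FALSE))
#' @export
prAuc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), is.logical(truth))
  P <- sum(truth)
  if (P == 0L) {
    return(0)
  }
  if (length(unique(scores)) == 1L) {
    warning("all scores equal; returning positive prevalence")
    return(mean(truth))
  }
  ord <- order(-scores, truth) # within ties: negatives first (worst case)
  pos <- truth[ord]
  prec <- cumsum(pos) / seq_along(pos)
  sum(prec[pos]) / P
}

scenarioLabel <- function(scn) {
  if (is(scn, "LatentScenario")) {
    sprintf("latent(n=%d, p=%s, pc=%s)", scn@n,
            paste(scn@p, collapse = "/"), paste(scn@pc, collapse = "/"))
  } else {
    sprintf("nonlinear(n=%d, p2c=%d, g=%d)", scn@n, scn@p2c, scn@g)
  }
}

reSeed <- function(scn, seed) {
  scn@seed <- seed
  scn
}

# per-replicate two-omics evaluation of all requested methods
evalTwoOmicsReplicate <- function(sim, params, methods, tauGrid, kRepeats,
                                  pr, alpha) {
  X <- sim@datasets[[1]]
  Y <- sim@datasets[[2]]
  truthX <- sim@truth[[1]]
  truthY <- sim@truth[[2]]
  forest <- mrfForest(X, Y, params)
  prof <- imdProfiles(forest)
  out <- list()
  for (method in methods) {
    sel <- switch(method,
      filter = {
        s <- selectFilter(forest, X, Y, tauGrid = tauGrid,
                          kRepeats = kRepeats)
        list(p = selectedIds(s$predictor), q = selectedIds(s$response))
      },
      mixture = list(
        p = selectedIds(selectMixture(prof$predictor, pr = pr)),
        q = selectedIds(selectMixture(prof$response, pr = pr))
      ),
      transformation = list(
        p = selectedIds(selectTransformation(prof$predictor, alpha = alpha)),
        q = selectedIds(selectTransformation(prof$response, alpha = alpha))
      ),
      stop("unknown method: ", method)
    )
    crX <- confusionAndRates(sel$p, truthX)
    crY <- confusionAndRates(sel$q, truthY)
    scoreX <- if (method == "transformation") {
      tscoreImd(prof$predictor)
    } else {
      forestImd(prof$predictor)
    }
    scoreY <- if (method == "transformation") {
      tscoreImd(prof$response)
    } else {
      forestImd(prof$response)
    }
    # +-Inf t-scores are decisive end ranks; map to finite sentinels
    scoreX[scoreX == Inf] <- .Machine$double.xmax
    scoreX[scoreX == -Inf] <- -.Machine$double.xmax
    scoreY[scoreY == Inf] <- .Machine$double.xmax
    scoreY[scoreY == -Inf] <- -.Machine$double.xmax
    out[[method]] <- data.frame(
      method = method,
      pr_auc = mean(c(prAuc(scoreX, unname(truthX)),
                      prAuc(scoreY, unname(truthY)))),
      precision = mean(c(as.numeric(crX$precision),
                         as.numeric(crY$precision))),
      recall = mean(c(crX$recall, crY$recall)),
      model_size = length(sel$p) + length(sel$q)
    )
  }
  do.call(rbind, out)
}

#' Run a simulation scenario benchmark
#'
#' Per replicate: generate data at a derived seed, fit the forest
#' (two-omics: first dataset as predictors, second as responses; three
#' datasets: the full integration pipeline), apply each selection method,
#' and score recall, precision, PR-AUC (ranking by forest IMD for
#' filter/mixture and by t-score for the transformation, averaged over
#' datasets), and total model size. Means and standard deviations over
#' replicates are reported; the per-replicate table is attached as the
#' `"replicates"` attribute.
#'
#' @param scenario a [LatentScenario-class] or [NonlinearScenario-class].
#' @param methods subset of `c("filter", "mixture", "transformation")`.
#' @param replicates number of simulation replicates.
#' @param seed master seed; replicate seeds are derived from it.
#' @param params [ForestParams-class] template (its seed is re-derived per
#'   replicate).
#' @param tauGrid,kRepeats,pr,alpha selection-rule controls.
#' @return data.frame with one row per method: mean and sd of each metric
#'   (sd is `NA` when `replicates = 1`).
#' @export
runScenario <- function(scenario, methods = c("filter", "mixture",
                                              "transformation"),
                        replicates = 20L, seed = 1L,
                        params = forestParams(),
                        tauGrid = seq(0.1, 3, by = 0.1), kRepeats = 5L,
                        pr = 0.05, alpha = 0.05) {
  stopifnot(replicates >= 1L)
  logs <- list()
  failures <- 0L
  for (r in seq_len(replicates)) {
    res <- tryCatch(
      {
        sim <- simulateData(reSeed(scenario, deriveSeed(seed, r)))
        pr_r <- params
        pr_r@seed <- deriveSeed(seed, r, 2L)
        if (length(sim@datasets) == 2L) {
          tab <- evalTwoOmicsReplicate(sim, pr_r, methods, tauGrid,
                                       kRepeats, pr, alpha)
        } else {
          tab <- evalIntegrationReplicate(sim, pr_r, methods, tauGrid,
                                          kRepeats, pr, alpha)
        }
        tab$replicate <- r
        tab
      },
      error = function(e) {
        warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) failures <- failures + 1L else logs[[length(logs) + 1L]] <- res
  }
  if (length(logs) == 0L) stop("all replicates failed")
  perRep <- do.call(rbind, logs)
  rownames(perRep) <- NULL

  agg <- lapply(split(perRep, perRep$method), function(d) {
    one <- function(v) {
      c(mean = mean(v), sd = if (nrow(d) > 1L) sd(v) else NA_real_)
    }
    data.frame(
      method = d$method[1], scenario = scenarioLabel(scenario),
      replicates = nrow(d),
      pr_auc_mean = one(d$pr_auc)[1], pr_auc_sd = one(d$pr_auc)[2],
      precision_mean = one(d$precision)[1],
      precision_sd = one(d$precision)[2],
      recall_mean = one(d$recall)[1], recall_sd = one(d$recall)[2],
      model_size_mean = one(d$model_size)[1],
      model_size_sd = one(d$model_size)[2]
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  attr(out, "replicates") <- perRep
  attr(out, "failures") <- failures
  out
}

# K >= 3: integrate and score the per-dataset selections; PR-AUC ranks by
# the aggregated mean IMD (t-score votes have no single score, so the
# transformation also falls back to mean IMD for ranking)
evalIntegrationReplicate <- function(sim, params, methods, tauGrid,
                                     kRepeats, pr, alpha) {
  models <- chooseDirections(sim@datasets, params)
  meanImd <- meanImdProfiles(models)
  out <- list()
  for (method in methods) {
    sels <- aggregateAndSelect(models, sim@datasets, method,
                               tauGrid = tauGrid, kRepeats = kRepeats,
                               pr = pr, alpha = alpha)
    rec <- prec <- auc <- numeric(0)
    size <- 0L
    for (tag in names(sim@datasets)) {
      cr <- confusionAndRates(selectedIds(sels[[tag]]), sim@truth[[tag]])
      rec <- c(rec, cr$recall)
      prec <- c(prec, as.numeric(cr$precision))
      auc <- c(auc, prAuc(meanImd[[tag]], unname(sim@truth[[tag]])))
      size <- size + length(selectedIds(sels[[tag]]))
    }
    out[[method]] <- data.frame(
      method = method, pr_auc = mean(auc), precision = mean(prec),
      recall = mean(rec), model_size = size
    )
  }
  do.call(rbind, out)
}
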