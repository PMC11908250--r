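#' @include AllClasses.R
NULL

#' Accessors for momirf objects
#'
#' Small accessor generics so slots are never reached into directly:
#' `nTrees()` returns the tree count of a forest, `forestImd()` the
#' per-variable forest IMD of a profile, `tscoreImd()` its t-scores,
#' `perTreeImd()` the trees x variables IMD matrix, `featureIds()` the
#' variable identifiers, `selectedIds()` the variables a selection rule
#' kept, `datasets()`/`truthMask()` the matrices and truth labels of a
#' simulated data set, and `meanOobError()` the mean OOB error of a
#' report (or of two raw error vectors).
#'
#' @param x,object a momirf object.
#' @param ... further arguments for methods.
#' @return the accessed component.
#' @name accessors
#' @aliases nTrees forestImd tscoreImd perTreeImd featureIds selectedIds
#'   datasets truthMask meanOobError
NULL

#' @rdname accessors
#' @export
setGeneric("nTrees", function(x) standardGeneric("nTrees"))

#' @rdname accessors
#' @export
setGeneric("forestImd", function(x) standardGeneric("forestImd"))

#' @rdname accessors
#' @export
setGeneric("tscoreImd", function(x) standardGeneric("tscoreImd"))

#' @rdname accessors
#' @export
setGeneric("perTreeImd", function(x) standardGeneric("perTreeImd"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("selectedIds", function(x) standardGeneric("selectedIds"))

#' @rdname accessors
#' @export
setGeneric("datasets", function(x) standardGeneric("datasets"))

#' @rdname accessors
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))

#' @rdname accessors
#' @export
setGeneric("meanOobError", function(x, ...) standardGeneric("meanOobError"))

#' @rdname accessors
#' @export
setMethod("nTrees", "MrfForest", function(x) length(x@trees))

#' @rdname accessors
#' @export
setMethod("forestImd", "ImdProfile", function(x) {
  setNames(x@forestImd, x@featureIds)
})

#' @rdname accessors
#' @export
setMethod("tscoreImd", "ImdProfile", function(x) {
  setNames(x@tscore, x@featureIds)
})

#' @rdname accessors
#' @export
setMethod("perTreeImd", "ImdProfile", function(x) x@perTreeImd)

#' @rdname accessors
#' @export
setMethod("featureIds", "ImdProfile", function(x) x@featureIds)

#' @rdname accessors
#' @export
setMethod("selectedIds", "SelectionResult", function(x) x@selectedIds)

#' @rdname accessors
#' @export
setMethod("datasets", "SimulatedData", function(x) x@datasets)

#' @rdname accessors
#' @export
setMethod("truthMask", "SimulatedData", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("meanOobError", "OobReport", function(x, ...) x@meanErr)

#' @rdname accessors
#' @export
setMethod("meanOobError", "numeric", function(x, ...) {
  # numeric method: mean over the concatenation of all supplied error
  # vectors, e.g. meanOobError(perResponseErr, perPredictorErr)
  mean(c(x, unlist(list(...))))
})

# ----------------------------------------------------------------- show ----

setMethod("show", "ForestParams", function(object) {
  cat(
    "ForestParams: ntree=", object@ntree, ", mtry=",
    ifelse(is.na(object@mtry), "ceiling(p/3)", object@mtry),
    ", respFrac=", object@respFrac, ", nodesize=", object@nodesize,
    ", nsplit=", object@nsplit, ", seed=", object@seed, "\n",
    sep = ""
  )
})

setMethod("show", "MrfForest", function(object) {
  cat("MrfForest with", length(object@trees), "trees\n")
  cat("  samples:", object@n, " predictors:", object@p,
      " responses:", object@q, "\n")
  cat("  mtry:", object@mtryUsed, " nodesize:", object@params@nodesize,
      " seed:", object@params@seed, "\n")
})

setMethod("show", "ImdProfile", function(object) {
  cat("ImdProfile (", object@side, " side): ",
    length(object@featureIds), " variables, ",
    nrow(object@perTreeImd), " trees\n",
    sep = ""
  )
  cat("  grand mean IMD:", format(object@mu, digits = 4), "\n")
  top <- head(order(object@forestImd, decreasing = TRUE), 5L)
  cat("  top variables:",
      paste(object@featureIds[top], collapse = ", "), "\n")
})

setMethod("show", "OobReport", function(object) {
  cat("OobReport: mean OOB error", format(object@meanErr, digits = 5),
      "over", length(object@perPredictorErr), "predictors and",
      length(object@perResponseErr), "responses\n")
})

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit (", object@modelKind, "): p0=",
    format(object@p0, digits = 4), ", p=", format(object@p, digits = 4),
    "\n  comp1: N(", format(object@mu1, digits = 4), ", ",
    format(object@sigma1, digits = 4), ")  comp2: N(",
    format(object@mu2, digits = 4), ", ",
    format(object@sigma2, digits = 4), ")\n  loglik ",
    format(object@loglik, digits = 6), " after ", object@nIter,
    " iterations (converged: ", object@converged, ")\n",
    sep = ""
  )
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult [", object@method, ", ", object@side, "]: ",
    length(object@selectedIds), " variables selected (threshold ",
    format(object@threshold[1], digits = 4), ")\n",
    sep = ""
  )
})

setMethod("show", "SimulatedData", function(object) {
  cat("SimulatedData with", length(object@datasets), "datasets\n")
  for (tag in names(object@datasets)) {
    d <- object@datasets[[tag]]
    cat("  ", tag, ": ", nrow(d), " x ", ncol(d), " (",
      sum(object@truth[[tag]]), " true)\n",
      sep = ""
    )
  }
})

setMethod("show", "DirectionModel", function(object) {
  cat("DirectionModel: ", object@responseTag, " <- ",
    object@predictorTag, " (mean OOB ",
    format(object@meanOob, digits = 5), ")\n",
    sep = ""
  )
})

setMethod("show", "IntegrationResult", function(object) {
  cat("IntegrationResult with", length(object@models), "direction models\n")
  for (m in object@models) show(m)
  for (tag in names(object@selections)) {
    cat("  ", tag, ": ", length(object@selections[[tag]]@selectedIds),
      " variables selected\n",
      sep = ""
    )
  }
})
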