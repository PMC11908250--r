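#' @include forest.R
NULL

#' Read an omics matrix from delimited text
#'
#' Expects a header row of feature ids and sample ids in the first column.
#' Missing values, non-numeric cells, duplicated ids, and ragged rows are
#' rejected with row/column context (features with missing values must be
#' removed upstream).
#'
#' @param path file path.
#' @param sep field separator (default tab; use `","` for CSV).
#' @return numeric samples x features matrix with dimnames.
#' @export
readOmicsMatrix <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("matrix file needs sample ids plus >= 1 feature")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(colnames(df)[-1])) {
    stop("duplicated feature ids in header")
  }
  M <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, colnames(df)[-1]))
  for (j in 2L:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric or missing value in column '%s', row '%s'",
        colnames(df)[j], ids[bad[1]]
      ))
    }
    M[, j - 1L] <- v
  }
  M
}

#' Write an omics matrix as delimited text
#'
#' Inverse of [readOmicsMatrix()]: header row of feature ids, first column
#' of sample ids.
#'
#' @param M numeric matrix with dimnames.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
writeOmicsMatrix <- function(M, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

treeToJson <- function(tr) {
  list(
    inbag = tr$inbag, depth = tr$depth, splitVar = tr$splitVar,
    splitValue = tr$splitValue, msrv = tr$msrv, gqStar = tr$gqStar,
    left = tr$left, right = tr$right, nNode = tr$nNode
  )
}

treeFromJson <- function(tr) {
  asInt <- function(v) {
    v <- unlist(lapply(v, function(x) if (is.null(x)) NA_integer_ else x))
    as.integer(v)
  }
  asNum <- function(v) {
    v <- unlist(lapply(v, function(x) if (is.null(x)) NA_real_ else x))
    as.numeric(v)
  }
  list(
    inbag = asInt(tr$inbag), depth = asInt(tr$depth),
    splitVar = asInt(tr$splitVar), splitValue = asNum(tr$splitValue),
    msrv = asInt(tr$msrv), gqStar = asNum(tr$gqStar),
    left = asInt(tr$left), right = asInt(tr$right), nNode = asInt(tr$nNode)
  )
}

#' Serialize a forest to JSON
#'
#' Writes a versioned, schema-tagged JSON document with the parameters,
#' dimensions, feature ids, and flattened node tables of every tree, at
#' full numeric precision so a round trip through [readForest()]
#' reproduces identical IMD profiles and predictions.
#'
#' @param forest an [MrfForest-class].
#' @param path output path.
#' @export
writeForest <- function(forest, path) {
  pm <- forest@params
  doc <- list(
    schema = "momirf-forest/1",
    params = list(
      ntree = pm@ntree, mtry = pm@mtry, respFrac = pm@respFrac,
      nodesize = pm@nodesize, maxDepth = pm@maxDepth, nsplit = pm@nsplit,
      seed = pm@seed
    ),
    mtryUsed = forest@mtryUsed,
    n = forest@n, p = forest@p, q = forest@q,
    predictorIds = forest@predictorIds, responseIds = forest@responseIds,
    trees = lapply(forest@trees, treeToJson)
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' Read a forest serialized by [writeForest()]
#'
#' @param path JSON path.
#' @return an [MrfForest-class].
#' @export
readForest <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, "momirf-forest/1")) {
    stop("unrecognized forest schema")
  }
  pm <- doc$params
  params <- forestParams(
    ntree = pm$ntree,
    mtry = if (is.null(pm$mtry)) NA_integer_ else pm$mtry,
    respFrac = pm$respFrac, nodesize = pm$nodesize,
    maxDepth = if (is.null(pm$maxDepth)) NA_integer_ else pm$maxDepth,
    nsplit = pm$nsplit, seed = pm$seed
  )
  new("MrfForest",
    trees = lapply(doc$trees, treeFromJson), params = params,
    mtryUsed = as.integer(doc$mtryUsed), n = as.integer(doc$n),
    p = as.integer(doc$p), q = as.integer(doc$q),
    predictorIds = unlist(doc$predictorIds),
    responseIds = unlist(doc$responseIds)
  )
}

#' Write a result object with a schema tag and parameter echo
#'
#' Data frames (e.g. benchmark tables) are written as TSV; selection
#' results, OOB reports, and mixture fits as JSON carrying the method
#' parameters so a run can be replayed from its output.
#'
#' @param obj the result object.
#' @param path output path.
#' @export
writeResults <- function(obj, path) {
  if (is.data.frame(obj)) {
    write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  doc <- if (is(obj, "SelectionResult")) {
    list(
      schema = "momirf-selection/1", method = obj@method, side = obj@side,
      threshold = as.list(obj@threshold), selectedIds = obj@selectedIds
    )
  } else if (is(obj, "OobReport")) {
    list(
      schema = "momirf-oob/1", meanErr = obj@meanErr,
      perResponseErr = as.list(obj@perResponseErr),
      perPredictorErr = as.list(obj@perPredictorErr)
    )
  } else if (is(obj, "MixtureFit")) {
    list(
      schema = "momirf-mixture/1", modelKind = obj@modelKind,
      p0 = obj@p0, p = obj@p, mu1 = obj@mu1, sigma1 = obj@sigma1,
      mu2 = obj@mu2, sigma2 = obj@sigma2, loglik = obj@loglik,
      converged = obj@converged
    )
  } else {
    stop("no serializer for class ", class(obj)[1])
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
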