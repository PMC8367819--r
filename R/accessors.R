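#' Accessors for CohortTable
#'
#' @param x a [CohortTable].
#' @return `nSubjects` the subject count; `cohortValues` the raw
#'   data.frame of feature values; `cohortSchema` the schema data.frame;
#'   `cohortLabels` the class factor; `subjectIds` the identifiers;
#'   `missingMask` an N x D logical matrix, TRUE where a cell is missing.
#' @name CohortTable-accessors
NULL

#' @rdname CohortTable-accessors
setMethod("nSubjects", "CohortTable", function(x) nrow(x@values))

#' @rdname CohortTable-accessors
setMethod("cohortValues", "CohortTable", function(x) x@values)

#' @rdname CohortTable-accessors
setMethod("cohortSchema", "CohortTable", function(x) x@schema)

#' @rdname CohortTable-accessors
setMethod("cohortLabels", "CohortTable", function(x) x@labels)

#' @rdname CohortTable-accessors
setMethod("subjectIds", "CohortTable", function(x) x@ids)

#' @rdname CohortTable-accessors
setMethod("missingMask", "CohortTable", function(x) {
  m <- is.na(as.matrix(x@values))
  dimnames(m) <- list(x@ids, names(x@values))
  m
})

setMethod("show", "CohortTable", function(object) {
  sc <- object@schema
  feat <- schemaFeatures(sc)
  cat(sprintf(
    "CohortTable: %d subjects x %d features (%d continuous, %d binary, %d categorical)\n",
    nSubjects(object), nrow(feat),
    sum(feat$kind == "continuous"), sum(feat$kind == "binary"),
    sum(feat$kind == "categorical")
  ))
  tab <- table(object@labels)
  cat("classes: ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n", sep = "")
  frac <- mean(missingMask(object))
  cat(sprintf("missing cells: %.1f%%\n", 100 * frac))
  meta <- sc$name[sc$role == "meta"]
  if (length(meta)) cat("meta features:", paste(meta, collapse = ", "), "\n")
})

#' Accessors for FeatureMatrix
#'
#' @param x a [FeatureMatrix].
#' @return `featureValues` the numeric N x d matrix; `featureOrigin`
#'   the source feature name of every encoded column.
#' @name FeatureMatrix-accessors
NULL

#' @rdname FeatureMatrix-accessors
setMethod("featureValues", "FeatureMatrix", function(x) x@X)

#' @rdname FeatureMatrix-accessors
setMethod("featureOrigin", "FeatureMatrix", function(x) x@origin)

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf(
    "FeatureMatrix: %d x %d (%d source features)%s\n",
    nrow(object@X), ncol(object@X), length(unique(object@origin)),
    if (anyNA(object@X)) ", un-imputed (contains NA)" else ""
  ))
})

setMethod("show", "PreprocessPlan", function(object) {
  cat(sprintf(
    "PreprocessPlan: %d encoded columns from %d features; %d dropped (missingness >= %.0f%%)\n",
    nrow(object@columns), length(unique(object@columns$source)),
    length(object@dropped), 100 * object@dropThreshold
  ))
  if (length(object@dropped)) cat("dropped:", paste(object@dropped, collapse = ", "), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf(
    "ModelSpec %s [%s%s]: %d fixed, %d searchable parameters\n",
    object@name, object@family, if (object@transductive) ", transductive" else "",
    length(object@fixedParams), length(object@searchSpace)
  ))
})

setMethod("show", "FittedModel", function(object) {
  cat(sprintf(
    "FittedModel %s: d = %d, classes = %s\n",
    object@spec@name, object@trainDim, paste(object@classes, collapse = "/")
  ))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf(
    "FoldPlan: %d subjects in %d folds (test sizes %s)\n",
    length(object@assignment), object@k,
    paste(range(tabulate(object@assignment, object@k)), collapse = "-")
  ))
})

setMethod("show", "MetaGraphSet", function(object) {
  n <- if (length(object@graphs)) nrow(object@graphs[[1]]) else 0
  cat(sprintf("MetaGraphSet: %d graphs over %d subjects\n", length(object@graphs), n))
  for (i in seq_along(object@graphs)) {
    r <- object@rules[i, ]
    cat(sprintf(
      "  %s (%s%s): %d edges\n", r$meta, r$type,
      if (r$type == "abs_diff") sprintf(" <= %g", r$threshold) else "",
      sum(object@graphs[[i]]) / 2
    ))
  }
})

#' Accessors for BenchmarkResult
#'
#' @param x a [BenchmarkResult].
#' @return `benchmarkMetrics` the tidy per-fold metric table;
#'   `pooledPredictions` one out-of-fold prediction per subject and
#'   classifier; `foldImportances` per-classifier fold x d importance
#'   matrices; `benchmarkFailures` the per-fold failure log.
#' @name BenchmarkResult-accessors
NULL

#' @rdname BenchmarkResult-accessors
setMethod("benchmarkMetrics", "BenchmarkResult", function(x) x@metrics)

#' @rdname BenchmarkResult-accessors
setMethod("pooledPredictions", "BenchmarkResult", function(x) x@predictions)

#' @rdname BenchmarkResult-accessors
setMethod("foldImportances", "BenchmarkResult", function(x) x@importances)

#' @rdname BenchmarkResult-accessors
setMethod("benchmarkFailures", "BenchmarkResult", function(x) x@failures)

setMethod("show", "BenchmarkResult", function(object) {
  cls <- unique(object@metrics$classifier)
  cat(sprintf(
    "BenchmarkResult: %d classifiers x %d folds, %d subjects\n",
    length(cls), object@foldPlan@k, length(object@foldPlan@assignment)
  ))
  acc <- object@metrics[object@metrics$metric == "accuracy", ]
  if (nrow(acc)) {
    agg <- vapply(split(acc$value, acc$classifier), mean, numeric(1))
    agg <- sort(agg, decreasing = TRUE)
    for (nm in names(agg)) cat(sprintf("  %-5s mean accuracy %.3f\n", nm, agg[[nm]]))
  }
  if (nrow(object@failures)) {
    cat(sprintf("failures: %d (see benchmarkFailures())\n", nrow(object@failures)))
  }
})

setMethod("show", "AggregatedImportance", function(object) {
  cat(sprintf(
    "AggregatedImportance: %d features aggregated over %d classifiers\n",
    length(object@I0), nrow(object@contributions)
  ))
  k <- min(10L, length(object@ranking))
  cat("top features:", paste(object@ranking[seq_len(k)], collapse = ", "), "\n")
})
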