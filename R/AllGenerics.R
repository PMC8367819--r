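#' @rdname CohortTable-accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname CohortTable-accessors
#' @export
setGeneric("cohortValues", function(x) standardGeneric("cohortValues"))

#' @rdname CohortTable-accessors
#' @export
setGeneric("cohortSchema", function(x) standardGeneric("cohortSchema"))

#' @rdname CohortTable-accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))

#' @rdname CohortTable-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname CohortTable-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureOrigin", function(x) standardGeneric("featureOrigin"))

#' Fit a classifier from the registry
#'
#' @param spec a [ModelSpec].
#' @param X numeric design matrix (no missing entries) or, for the
#'   transductive MGMC model, a list carrying the full matrix and masks.
#' @param y factor of class labels for the training rows.
#' @param seed integer seed for stochastic trainers.
#' @param ... further arguments for individual trainers.
#' @return a [FittedModel].
#' @export
setGeneric("fitModel", function(spec, X, y, seed = 1L, ...) standardGeneric("fitModel"))

#' Class-probability predictions
#'
#' @param model a [FittedModel].
#' @param X numeric matrix with `trainDim(model)` columns.
#' @return N x C matrix of probabilities; columns follow `model@classes`
#'   and every row sums to one.
#' @export
setGeneric("predictProba", function(model, X) standardGeneric("predictProba"))

#' @rdname BenchmarkResult-accessors
#' @export
setGeneric("benchmarkMetrics", function(x) standardGeneric("benchmarkMetrics"))

#' @rdname BenchmarkResult-accessors
#' @export
setGeneric("pooledPredictions", function(x) standardGeneric("pooledPredictions"))

#' @rdname BenchmarkResult-accessors
#' @export
setGeneric("foldImportances", function(x) standardGeneric("foldImportances"))

#' @rdname BenchmarkResult-accessors
#' @export
setGeneric("benchmarkFailures", function(x) standardGeneric("benchmarkFailures"))
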