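#' @import methods
#' @importFrom stats predict quantile sd var rnorm runif rbinom aov
#'   chisq.test kruskal.test shapiro.test t.test wilcox.test prcomp
#'   coef glm binomial plogis setNames complete.cases p.adjust
#' @importFrom utils read.table write.table head modifyList
NULL

KIND_LEVELS <- c("continuous", "binary", "categorical")
ROLE_LEVELS <- c("feature", "label", "meta", "ignore")

#' CohortTable: a mixed-type patient-by-feature table
#'
#' Central container for a clinical cohort: one row per subject, one
#' column per declared feature. Continuous features are stored as
#' numeric columns, binary/categorical features as character columns;
#' `NA` marks a missing cell. The class label is carried separately and
#' may never be missing.
#'
#' @slot values data.frame of raw feature values (N x D), `NA` = missing.
#' @slot schema data.frame describing each column: `name`, `kind`
#'   (continuous/binary/categorical), `role` (feature/label/meta/ignore)
#'   and a `categories` list column (category levels, categorical only).
#' @slot labels factor of length N with the class of each subject.
#' @slot ids character subject identifiers (0-based row index when the
#'   source file declares none).
#' @export
setClass("CohortTable", representation(
  values = "data.frame",
  schema = "data.frame",
  labels = "factor",
  ids = "character"
))

setValidity("CohortTable", function(object) {
  msg <- character()
  sc <- object@schema
  need <- c("name", "kind", "role", "categories")
  if (!all(need %in% names(sc))) {
    return(sprintf("schema must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(sc$name)) msg <- c(msg, "schema names must be unique")
  if (!all(sc$kind %in% KIND_LEVELS)) msg <- c(msg, "unknown feature kind in schema")
  if (!all(sc$role %in% ROLE_LEVELS)) msg <- c(msg, "unknown role in schema")
  feat <- schemaFeatures(sc)
  if (!all(feat$name %in% names(object@values))) {
    msg <- c(msg, "values must contain one column per schema feature")
  }
  n <- nrow(object@values)
  if (n < 1) msg <- c(msg, "cohort must contain at least one subject")
  if (length(object@labels) != n) msg <- c(msg, "labels length must equal row count")
  if (anyNA(object@labels)) msg <- c(msg, "labels may not be missing")
  if (nlevels(object@labels) < 2) msg <- c(msg, "at least two classes are required")
  if (length(object@ids) != n) msg <- c(msg, "ids length must equal row count")
  for (i in seq_len(nrow(feat))) {
    fi <- feat[i, ]
    col <- object@values[[fi$name]]
    if (fi$kind == "continuous" && !is.numeric(col)) {
      msg <- c(msg, sprintf("continuous feature '%s' must be numeric", fi$name))
    }
    if (fi$kind != "continuous") {
      cats <- fi$categories[[1]]
      if (length(cats) < 2) {
        msg <- c(msg, sprintf("feature '%s' needs >= 2 categories", fi$name))
      }
      bad <- !is.na(col) & !(col %in% cats)
      if (any(bad)) {
        msg <- c(msg, sprintf("feature '%s' has labels outside its categories", fi$name))
      }
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

# schema rows that carry data columns (features and meta features)
schemaFeatures <- function(schema) {
  schema[schema$role %in% c("feature", "meta"), , drop = FALSE]
}

#' PreprocessPlan: fitted preprocessing statistics
#'
#' Everything learned from a training partition that is needed to map a
#' [CohortTable] into a numeric [FeatureMatrix]: winsorization bounds
#' and standardization statistics per continuous feature, the
#' category-to-column map per categorical feature, one imputation value
#' per encoded column, and the list of features dropped by the
#' missingness rule.
#'
#' @slot continuous data.frame with one row per retained continuous
#'   feature: `name`, clip bounds `lower`/`upper`, standardization
#'   `center`/`scale`, `constant` flag.
#' @slot columns data.frame with one row per encoded output column:
#'   `column`, `source` feature, `category` (NA for continuous and the
#'   positive level for binarized features) and `impute` value.
#' @slot catmaps named list mapping categorical feature -> category levels.
#' @slot dropped character, features with fit-time missingness at or
#'   above the threshold.
#' @slot dropThreshold numeric in (0, 1].
#' @slot percentiles numeric length 2, winsorization percentiles.
#' @slot missingReport data.frame of per-feature fit missingness fractions.
#' @export
setClass("PreprocessPlan", representation(
  continuous = "data.frame",
  columns = "data.frame",
  catmaps = "list",
  dropped = "character",
  dropThreshold = "numeric",
  percentiles = "numeric",
  missingReport = "data.frame"
))

setValidity("PreprocessPlan", function(object) {
  msg <- character()
  co <- object@continuous
  if (nrow(co)) {
    if (any(co$lower > co$upper)) msg <- c(msg, "clip lower must be <= upper")
    if (any(!co$constant & co$scale <= 0)) {
      msg <- c(msg, "retained non-constant features need positive s.d.")
    }
  }
  if (length(intersect(object@dropped, object@columns$source))) {
    msg <- c(msg, "dropped features may not appear among encoded columns")
  }
  if (object@dropThreshold <= 0 || object@dropThreshold > 1) {
    msg <- c(msg, "dropThreshold must lie in (0, 1]")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' FeatureMatrix: fully numeric encoded design matrix
#'
#' @slot X numeric matrix, N x d (encoded dimensionality). Contains no
#'   missing entries after a standard [applyPreprocess()] call; the
#'   un-imputed variant (`impute = FALSE`) keeps `NA` at unobserved cells.
#' @slot origin character of length d, source feature of every column.
#' @export
setClass("FeatureMatrix", representation(
  X = "matrix",
  origin = "character"
))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (ncol(object@X) < 1) msg <- c(msg, "feature matrix needs >= 1 column")
  if (length(object@origin) != ncol(object@X)) {
    msg <- c(msg, "origin must name the source of every column")
  }
  if (is.null(colnames(object@X))) msg <- c(msg, "columns must be named")
  if (any(!is.na(object@X) & !is.finite(object@X))) {
    msg <- c(msg, "entries must be finite or NA")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' FoldPlan: a stratified cross-validation assignment
#'
#' @slot k integer fold count.
#' @slot assignment integer vector in 1..k, fold of each subject.
#' @slot seed integer seed used to deal subjects.
#' @export
setClass("FoldPlan", representation(
  k = "integer",
  assignment = "integer",
  seed = "integer"
))

setValidity("FoldPlan", function(object) {
  msg <- character()
  if (object@k < 2) msg <- c(msg, "k must be >= 2")
  if (any(object@assignment < 1L | object@assignment > object@k)) {
    msg <- c(msg, "assignments must lie in 1..k")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ModelSpec: declaration of one classifier in the registry
#'
#' @slot name short identifier (LDA, LR, SVC, GNB, GP, KNN, DT, RF, AB,
#'   MLP, MGMC).
#' @slot fixedParams named list of pinned settings that are never tuned
#'   (kernel, split criterion, architecture).
#' @slot defaultParams named list of default values for the tunable
#'   parameters; used whenever tuning is disabled or the search space is
#'   empty.
#' @slot searchSpace named list of samplers; each element is either a
#'   function(n) returning n sampled values or a vector of discrete
#'   choices. Empty list = fixed parametrization, no inner tuning.
#' @slot family one of linear/nonlinear/tree/instance/neural/graph;
#'   drives importance extraction.
#' @slot transductive logical; TRUE only for the graph matrix-completion
#'   model, which sees all rows but only training labels.
#' @export
setClass("ModelSpec", representation(
  name = "character",
  fixedParams = "list",
  defaultParams = "list",
  searchSpace = "list",
  family = "character",
  transductive = "logical"
))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (length(intersect(names(object@fixedParams), names(object@searchSpace)))) {
    msg <- c(msg, "fixed and searchable parameters must be disjoint")
  }
  if (!all(names(object@searchSpace) %in% names(object@defaultParams))) {
    msg <- c(msg, "every searchable parameter needs a default value")
  }
  if (object@transductive && object@name != "MGMC") {
    msg <- c(msg, "only MGMC may be transductive")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' FittedModel: a trained classifier with its class order
#'
#' @slot spec the [ModelSpec] it was built from (fixed params merged
#'   with the chosen hyperparameters).
#' @slot state opaque fitted state (library fit object or weight list).
#' @slot classes ordered class labels; probability columns follow it.
#' @slot trainDim integer d the model accepts.
#' @export
setClass("FittedModel", representation(
  spec = "ModelSpec",
  state = "list",
  classes = "character",
  trainDim = "integer"
))

#' MetaGraphSet: per-meta-feature patient adjacency matrices
#'
#' @slot graphs list of N x N symmetric 0/1 matrices with zero diagonal.
#' @slot rules data.frame with `meta` (column name), `type`
#'   ("equal" or "abs_diff") and `threshold` per graph.
#' @export
setClass("MetaGraphSet", representation(
  graphs = "list",
  rules = "data.frame"
))

setValidity("MetaGraphSet", function(object) {
  msg <- character()
  if (length(object@graphs) != nrow(object@rules)) {
    msg <- c(msg, "one rule per graph required")
  }
  for (g in object@graphs) {
    if (!isSymmetric(unname(g))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(g) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (!all(g %in% c(0, 1))) msg <- c(msg, "adjacency must be 0/1")
  }
  if (length(msg)) paste(unique(msg), collapse = "; ") else TRUE
})

#' BenchmarkResult: everything a benchmark run produced
#'
#' @slot metrics tidy data.frame (classifier, fold, metric, value); k
#'   rows per classifier and metric.
#' @slot predictions data.frame (classifier, fold, id, label, prediction)
#'   with exactly one out-of-fold prediction per subject and classifier.
#' @slot probabilities named list, per classifier an N x C matrix of
#'   pooled out-of-fold class probabilities in cohort row order.
#' @slot hyperparameters named list, per classifier a list of per-fold
#'   chosen settings.
#' @slot importances named list, per classifier a k x d matrix of
#'   per-fold importance vectors.
#' @slot failures data.frame (classifier, fold, message).
#' @slot foldPlan the [FoldPlan] used.
#' @slot featureNames character, the d encoded column names.
#' @slot featureOrigin character, source feature per encoded column.
#' @slot classes character, class order used throughout.
#' @slot config list: k, seed, search settings, preprocessing mode.
#' @export
setClass("BenchmarkResult", representation(
  metrics = "data.frame",
  predictions = "data.frame",
  probabilities = "list",
  hyperparameters = "list",
  importances = "list",
  failures = "data.frame",
  foldPlan = "FoldPlan",
  featureNames = "character",
  featureOrigin = "character",
  classes = "character",
  config = "list"
))

#' AggregatedImportance: RAFI-aggregated global feature importance
#'
#' @slot I0 named numeric, global importance per feature; sums to the
#'   number of contributing classifiers.
#' @slot ranking character, features by descending importance.
#' @slot contributions F x d matrix of per-classifier normalized
#'   absolute importances (each row sums to 1).
#' @export
setClass("AggregatedImportance", representation(
  I0 = "numeric",
  ranking = "character",
  contributions = "matrix"
))

setValidity("AggregatedImportance", function(object) {
  msg <- character()
  if (any(object@I0 < 0)) msg <- c(msg, "global importances must be nonnegative")
  if (length(object@ranking) != length(object@I0)) {
    msg <- c(msg, "ranking must permute the feature set")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
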