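#' Stratified k-fold assignment
#'
#' Within each class, members are shuffled by the seed and dealt
#' round-robin to the k folds, so per-fold class counts differ from
#' perfect stratification by at most one. A class with fewer members
#' than folds degrades to a warning and a best-effort assignment (some
#' folds then lack that class).
#'
#' @param labels length-N class vector.
#' @param k fold count, 2 <= k <= N (k = N gives leave-one-out).
#' @param seed integer seed.
#' @return a [FoldPlan].
#' @export
stratifiedFolds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (k > n) stop("k may not exceed the number of subjects")
  if (k < 2) stop("k must be >= 2")
  labels <- as.character(labels)
  assignment <- integer(n)
  withSeed(childSeed(seed, "folds"), {
    offset <- 0L # carried across classes so fold sizes stay balanced
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        warning(sprintf(
          "class '%s' has %d members (< k = %d); some folds will lack it",
          cl, length(idx), k
        ))
      }
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  new("FoldPlan", k = as.integer(k), assignment = assignment, seed = as.integer(seed))
}

#' Nested random-search configuration
#'
#' @param nIter candidate settings sampled per model (identical samples
#'   are evaluated once; ties in score go to the earliest sampled).
#' @param innerK inner stratified fold count (>= 2).
#' @param metric selection metric: accuracy, f1 or roc_auc.
#' @param seed integer seed.
#' @return list of class `SearchConfig`.
#' @export
searchConfig <- function(nIter = 30L, innerK = 3L,
                         metric = c("accuracy", "f1", "roc_auc"), seed = 1L) {
  metric <- match.arg(metric)
  if (nIter < 1) stop("nIter must be >= 1")
  if (innerK < 2) stop("innerK must be >= 2")
  structure(
    list(nIter = as.integer(nIter), innerK = as.integer(innerK),
      metric = metric, seed = as.integer(seed)),
    class = "SearchConfig"
  )
}

# evaluate one candidate setting by inner stratified CV; train is either a
# plain matrix or the transductive list input
evalSetting <- function(spec, train, y, setting, cfg, seed, positive = NULL) {
  innerPlan <- suppressWarnings(
    stratifiedFolds(y, cfg$innerK, childSeed(seed, "innerfolds"))
  )
  classes <- sort(unique(as.character(y)))
  scores <- vapply(seq_len(cfg$innerK), function(f) {
    testIdx <- which(innerPlan@assignment == f)
    trainIdx <- which(innerPlan@assignment != f)
    if (length(unique(as.character(y[trainIdx]))) < 2 || length(testIdx) == 0) {
      return(NA_real_)
    }
    if (spec@transductive) {
      yMasked <- as.character(y)
      yMasked[testIdx] <- NA
      model <- fitModel(spec,
        list(X = train$X, graphs = train$graphs, trainIdx = trainIdx,
          basis = train$basis),
        yMasked, seed = childSeed(seed, "innerfit", f), params = setting
      )
      probs <- predictProba(model, testIdx)
    } else {
      model <- fitModel(spec, train[trainIdx, , drop = FALSE], y[trainIdx],
        seed = childSeed(seed, "innerfit", f), params = setting
      )
      probs <- predictProba(model, train[testIdx, , drop = FALSE])
    }
    pr <- matrix(0, length(testIdx), length(classes),
      dimnames = list(NULL, classes)
    )
    pr[, colnames(probs)] <- probs
    pred <- classes[max.col(pr, ties.method = "first")]
    cm <- confusionMatrix(y[testIdx], pred, classes)
    m <- classificationMetrics(cm, pr, y[testIdx], positive = positive)
    m[[cfg$metric]]
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Random-search hyperparameter tuning on a training partition
#'
#' Samples `cfg$nIter` settings from the model's search space (seeded),
#' scores each unique setting by the inner stratified `cfg$innerK`-fold
#' mean of the selection metric on the training data only, and returns
#' the best; ties are broken by earliest sampled. Models with an empty
#' search space return their fixed defaults without running inner folds.
#'
#' @param spec a [ModelSpec].
#' @param train design matrix (or, transductive models, a list with the
#'   full matrix `X`, `graphs` and nothing else — rows are the training
#'   partition).
#' @param y training labels.
#' @param cfg a [searchConfig()].
#' @param seed integer seed.
#' @param positive positive class forwarded to the metric.
#' @return named list: the chosen hyperparameter setting (empty when
#'   the space is empty).
#' @export
randomSearch <- function(spec, train, y, cfg = searchConfig(), seed = 1L,
                         positive = NULL) {
  if (length(spec@searchSpace) == 0) return(list())
  settings <- withSeed(childSeed(seed, "sample", spec@name), {
    lapply(seq_len(cfg$nIter), function(i) sampleSetting(spec@searchSpace))
  })
  keys <- vapply(settings, function(s) paste(deparse(s), collapse = ""), character(1))
  settings <- settings[!duplicated(keys)]
  if (length(settings) == 1) return(settings[[1]])
  scores <- vapply(seq_along(settings), function(i) {
    evalSetting(spec, train, y, settings[[i]], cfg,
      childSeed(seed, "eval", spec@name, i), positive)
  }, numeric(1))
  scores[is.na(scores)] <- -Inf
  settings[[which.max(scores)]] # which.max takes the earliest on ties
}

#' Run the full benchmark
#'
#' For each outer fold: fits the preprocessing plan on the training
#' rows, transforms both partitions, tunes every registry model by
#' nested random search on the training partition, refits on the full
#' training partition and predicts the held-out fold. Transductive
#' models instead receive the full preprocessed (un-imputed) matrix with
#' every test label masked, plus the meta-feature patient graphs. The
#' result holds exactly one out-of-fold prediction per subject and k
#' metric estimates per classifier; a model that raises during a fold is
#' recorded as failed and the benchmark continues.
#'
#' @param table a [CohortTable].
#' @param registry named list of [ModelSpec] (default [defaultRegistry()]).
#' @param k outer fold count (default 10).
#' @param search a [searchConfig()].
#' @param seed master seed; every fold/model pair draws an independent
#'   child stream, so adding a model does not perturb the others.
#' @param preprocessing `"per_fold"` (fit on each training partition;
#'   leakage-safe default) or `"global"` (fit once on all rows).
#' @param dropThreshold missingness drop rule forwarded to
#'   [fitPreprocess()].
#' @param percentiles winsorization percentile pair forwarded to
#'   [fitPreprocess()].
#' @param graphRules meta-graph rules for transductive models; rules
#'   naming columns the cohort lacks are an error when such a model is
#'   in the registry.
#' @param transductiveInput what the transductive model consumes:
#'   `"raw"` (default) passes the un-imputed matrix with its
#'   missingness mask, so the model imputes jointly with classifying;
#'   `"imputed"` passes the mean-imputed matrix like every other model.
#' @return a [BenchmarkResult].
#' @export
runBenchmark <- function(table, registry = defaultRegistry(), k = 10L,
                         search = searchConfig(), seed = 1L,
                         preprocessing = c("per_fold", "global"),
                         dropThreshold = 0.5, percentiles = c(5, 95),
                         graphRules = defaultGraphRules(),
                         transductiveInput = c("raw", "imputed")) {
  preprocessing <- match.arg(preprocessing)
  transductiveInput <- match.arg(transductiveInput)
  if (length(registry) == 0) stop("registry may not be empty")
  labels <- as.character(cohortLabels(table))
  classes <- levels(cohortLabels(table))
  classes <- classes[classes %in% labels]
  n <- nSubjects(table)
  plan <- stratifiedFolds(labels, k, childSeed(seed, "outer"))
  positive <- if (length(classes) == 2) {
    counts <- table(factor(labels, levels = classes))
    classes[which.min(counts)]
  } else NULL

  anyTrans <- any(vapply(registry, function(s) s@transductive, logical(1)))
  fullGraphs <- NULL
  fullBasis <- NULL
  if (anyTrans) {
    rules <- graphRules[graphRules$meta %in% names(table@values), , drop = FALSE]
    if (nrow(rules) == 0) {
      stop("transductive model requested but no graph rule matches a cohort column")
    }
    fullGraphs <- buildMetaGraphs(table@values[, rules$meta, drop = FALSE], rules)
    fullBasis <- mgmcBasis(fullGraphs) # reused by every fold's final fit
  }
  globalPlan <- if (preprocessing == "global") {
    fitPreprocess(table, dropThreshold = dropThreshold, percentiles = percentiles)
  } else NULL
  # reference column space for aligning per-fold importances (folds may
  # drop different features around the missingness threshold)
  refPlan <- if (is.null(globalPlan)) {
    fitPreprocess(table, dropThreshold = dropThreshold, percentiles = percentiles)
  } else globalPlan
  refCols <- refPlan@columns$column

  metrics <- list(); predictions <- list(); failures <- list()
  hyper <- lapply(registry, function(x) vector("list", plan@k))
  probs <- lapply(registry, function(x) {
    matrix(NA_real_, n, length(classes), dimnames = list(table@ids, classes))
  })
  imps <- lapply(registry, function(x) {
    matrix(NA_real_, plan@k, length(refCols), dimnames = list(NULL, refCols))
  })

  for (f in seq_len(plan@k)) {
    testIdx <- which(plan@assignment == f)
    trainIdx <- which(plan@assignment != f)
    trainTab <- subsetCohort(table, trainIdx)
    pp <- if (is.null(globalPlan)) {
      fitPreprocess(trainTab, dropThreshold = dropThreshold, percentiles = percentiles)
    } else globalPlan
    Xtr <- featureValues(applyPreprocess(pp, trainTab))
    Xte <- featureValues(applyPreprocess(pp, subsetCohort(table, testIdx)))
    Xraw <- if (anyTrans) {
      featureValues(applyPreprocess(pp, table,
        impute = transductiveInput == "imputed"))
    } else NULL
    ytr <- factor(labels[trainIdx], levels = classes)

    for (nm in names(registry)) {
      spec <- registry[[nm]]
      mseed <- childSeed(seed, "fold", f, nm)
      res <- tryCatch({
        if (spec@transductive) {
          trainGraphs <- subsetGraphSet(fullGraphs, trainIdx)
          trainInput <- list(
            X = Xraw[trainIdx, , drop = FALSE],
            graphs = trainGraphs,
            basis = mgmcBasis(trainGraphs) # shared by all inner fits
          )
          setting <- randomSearch(spec, trainInput, ytr, search,
            seed = childSeed(mseed, "search"), positive = positive)
          yMasked <- labels
          yMasked[testIdx] <- NA
          model <- fitModel(spec,
            list(X = Xraw, graphs = fullGraphs, trainIdx = trainIdx,
              basis = fullBasis),
            yMasked, seed = mseed, params = setting
          )
          pr <- predictProba(model, testIdx)
          imp <- modelImportance(model,
            cfg = attributionConfig(seed = childSeed(mseed, "imp")))
        } else {
          setting <- randomSearch(spec, Xtr, ytr, search,
            seed = childSeed(mseed, "search"), positive = positive)
          model <- fitModel(spec, Xtr, ytr, seed = mseed, params = setting)
          pr <- predictProba(model, Xte)
          imp <- modelImportance(model, Xtr, ytr,
            cfg = attributionConfig(seed = childSeed(mseed, "imp")))
        }
        prFull <- matrix(0, length(testIdx), length(classes),
          dimnames = list(NULL, classes))
        prFull[, colnames(pr)] <- pr
        list(setting = setting, probs = prFull, imp = imp)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- data.frame(
          classifier = nm, fold = f, message = conditionMessage(res)
        )
        next
      }
      hyper[[nm]][[f]] <- res$setting
      probs[[nm]][testIdx, ] <- res$probs
      impNamed <- setNames(res$imp, pp@columns$column)
      shared <- intersect(names(impNamed), refCols)
      imps[[nm]][f, shared] <- impNamed[shared]
      pred <- classes[max.col(res$probs, ties.method = "first")]
      cm <- confusionMatrix(labels[testIdx], pred, classes)
      m <- classificationMetrics(cm, res$probs, labels[testIdx], positive = positive)
      for (mn in c("accuracy", "f1", "roc_auc", "f1_macro", "roc_auc_macro")) {
        metrics[[length(metrics) + 1]] <- data.frame(
          classifier = nm, fold = f, metric = mn, value = m[[mn]]
        )
      }
      predictions[[length(predictions) + 1]] <- data.frame(
        classifier = nm, fold = f, id = table@ids[testIdx],
        label = labels[testIdx], prediction = pred
      )
    }
  }

  new("BenchmarkResult",
    metrics = if (length(metrics)) do.call(rbind, metrics) else
      data.frame(classifier = character(), fold = integer(),
        metric = character(), value = numeric()),
    predictions = if (length(predictions)) do.call(rbind, predictions) else
      data.frame(),
    probabilities = probs,
    hyperparameters = hyper,
    importances = imps,
    failures = if (length(failures)) do.call(rbind, failures) else
      data.frame(classifier = character(), fold = integer(), message = character()),
    foldPlan = plan,
    featureNames = refCols,
    featureOrigin = refPlan@columns$source,
    classes = classes,
    config = list(
      k = plan@k, seed = seed, search = unclass(search),
      preprocessing = preprocessing, dropThreshold = dropThreshold,
      percentiles = percentiles, transductiveInput = transductiveInput,
      models = names(registry), positive = positive
    )
  )
}

subsetGraphSet <- function(graphs, idx) {
  new("MetaGraphSet",
    graphs = lapply(graphs@graphs, function(g) g[idx, idx, drop = FALSE]),
    rules = graphs@rules
  )
}

#' Pooled out-of-fold metrics per classifier
#'
#' Pools the single out-of-fold prediction of every subject and
#' recomputes the metric set per classifier (one number per classifier
#' rather than k estimates).
#'
#' @param result a [BenchmarkResult].
#' @return data.frame: classifier, accuracy, f1, roc_auc, n (subjects
#'   with a prediction).
#' @export
pooledMetrics <- function(result) {
  preds <- result@predictions
  rows <- lapply(unique(preds$classifier), function(nm) {
    sub <- preds[preds$classifier == nm, ]
    pr <- result@probabilities[[nm]]
    ok <- !is.na(pr[, 1])
    ids <- rownames(pr)[ok]
    sub <- sub[match(ids, sub$id), ]
    cm <- confusionMatrix(sub$label, sub$prediction, result@classes)
    m <- classificationMetrics(cm, pr[ok, , drop = FALSE], sub$label,
      positive = result@config$positive)
    data.frame(
      classifier = nm, accuracy = m$accuracy, f1 = m$f1,
      roc_auc = m$roc_auc, n = nrow(sub)
    )
  })
  do.call(rbind, rows)
}

#' Fold-averaged importance matrix across classifiers
#'
#' Averages each classifier's per-fold importance vectors and stacks
#' them into the F x d matrix consumed by [rafiAggregate()].
#'
#' @param result a [BenchmarkResult].
#' @param exclude classifiers to leave out of the matrix (e.g.
#'   `c("KNN", "GP", "GNB")` to aggregate only native importance
#'   recipes, excluding the permutation fallback).
#' @return list: `I` (F x d matrix) and `origin` (source feature per
#'   column, for one-hot pooling).
#' @export
importanceMatrix <- function(result, exclude = character()) {
  result@importances <- result@importances[
    !(names(result@importances) %in% exclude)
  ]
  rows <- lapply(names(result@importances), function(nm) {
    m <- result@importances[[nm]]
    if (is.null(m) || all(is.na(m))) return(NULL)
    v <- colMeans(m, na.rm = TRUE)
    v[is.nan(v)] <- 0
    v
  })
  keep <- !vapply(rows, is.null, logical(1))
  I <- do.call(rbind, rows[keep])
  rownames(I) <- names(result@importances)[keep]
  colnames(I) <- result@featureNames
  list(I = I, origin = result@featureOrigin)
}
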