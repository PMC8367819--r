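#' Confusion matrix
#'
#' @param yTrue,yPred label vectors of equal length; every label must
#'   appear in `classOrder`.
#' @param classOrder character vector fixing row/column order.
#' @return C x C integer matrix; rows are the true class, columns the
#'   predicted class, `counts[a, b] = #\{i : true = a, pred = b\}`.
#' @export
confusionMatrix <- function(yTrue, yPred, classOrder) {
  yTrue <- as.character(yTrue)
  yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred)) stop("yTrue and yPred must have equal length")
  bad <- setdiff(unique(c(yTrue, yPred)), classOrder)
  if (length(bad)) stop(sprintf("unknown label '%s'", bad[1]))
  cm <- table(
    factor(yTrue, levels = classOrder),
    factor(yPred, levels = classOrder)
  )
  m <- matrix(as.integer(cm), nrow = length(classOrder),
    dimnames = list(true = classOrder, predicted = classOrder)
  )
  m
}

# Mann-Whitney rank statistic form of the ROC-AUC; exact under ties
# (midranks). Returns NA when either class is absent.
aucRank <- function(scores, positive) {
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Classification metrics from a confusion matrix and probabilities
#'
#' Implements the usual count-based definitions: accuracy =
#' (TP + TN) / N, precision = TP / (TP + FP), recall = TP / (TP + FN),
#' f1 = 2 * Prec * Rec / (Prec + Rec), with f1 = 0 where Prec + Rec = 0.
#' Binary tasks report the f1 and ROC-AUC of the declared positive
#' class — by default the minority class, whose sensitivity is the
#' clinically informative one under imbalance — alongside macro
#' averages. Multi-class tasks report macro f1 and one-vs-rest
#' macro-averaged ROC-AUC.
#'
#' @param cm confusion matrix from [confusionMatrix()].
#' @param probs N x C probability matrix (columns in `cm` class order);
#'   rows must sum to 1.
#' @param yTrue true labels for the same N subjects (needed for AUC).
#' @param positive positive class for binary tasks; `NULL` picks the
#'   minority class by true count (ties broken by class order).
#' @return named list: `accuracy`, `f1`, `roc_auc`, `f1_macro`,
#'   `roc_auc_macro`, `precision`, `recall` (per-class named vectors),
#'   `positive`.
#' @export
classificationMetrics <- function(cm, probs = NULL, yTrue = NULL, positive = NULL) {
  classes <- rownames(cm)
  C <- length(classes)
  total <- sum(cm)
  accuracy <- sum(diag(cm)) / total
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  names(precision) <- names(recall) <- names(f1) <- classes

  aucs <- rep(NA_real_, C)
  names(aucs) <- classes
  if (!is.null(probs)) {
    if (is.null(dim(probs)) || ncol(probs) != C) {
      stop("probs must have one column per class")
    }
    if (any(abs(rowSums(probs) - 1) > 1e-6)) {
      stop("probability rows must sum to 1")
    }
    if (is.null(yTrue)) stop("yTrue is required for ROC-AUC")
    yTrue <- as.character(yTrue)
    for (ci in seq_len(C)) {
      aucs[ci] <- aucRank(probs[, ci], yTrue == classes[ci])
    }
  }
  if (C == 2) {
    if (is.null(positive)) {
      counts <- rowSums(cm)
      positive <- classes[which.min(counts)]
    }
    f1Main <- unname(f1[positive])
    aucMain <- unname(aucs[positive])
  } else {
    positive <- NA_character_
    f1Main <- mean(f1)
    aucMain <- mean(aucs, na.rm = TRUE)
  }
  list(
    accuracy = accuracy,
    f1 = f1Main,
    roc_auc = aucMain,
    f1_macro = mean(f1),
    roc_auc_macro = mean(aucs, na.rm = TRUE),
    precision = precision,
    recall = recall,
    positive = positive
  )
}

#' Seeded 2D embedding of the preprocessed input space
#'
#' Nonlinear 2D map (UMAP) of the encoded feature matrix, used in the
#' report panel to show whether class structure is already visible in
#' the input distribution. Cohorts smaller than 10 subjects fall back
#' to the first two principal axes with a warning.
#'
#' @param X numeric matrix or [FeatureMatrix] (no missing entries).
#' @param seed integer seed; identical seeds give identical coordinates.
#' @param nNeighbors UMAP neighborhood size (capped at N - 1).
#' @return N x 2 numeric matrix of coordinates.
#' @export
embed2d <- function(X, seed = 1L, nNeighbors = 15) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  if (anyNA(X)) stop("embedding input may not contain missing values")
  n <- nrow(X)
  if (n < 10) {
    warning("fewer than 10 subjects: falling back to the first two principal axes")
    p <- prcomp(X, center = TRUE, scale. = FALSE)
    co <- p$x[, seq_len(min(2, ncol(p$x))), drop = FALSE]
    if (ncol(co) < 2) co <- cbind(co, 0)
    colnames(co) <- c("dim1", "dim2")
    return(co)
  }
  co <- withSeed(childSeed(seed, "embed"), {
    uwot::umap(X,
      n_neighbors = min(nNeighbors, n - 1), n_components = 2,
      n_threads = 1, n_sgd_threads = 0, batch = FALSE, verbose = FALSE
    )
  })
  colnames(co) <- c("dim1", "dim2")
  co
}

#' Hypothesis test with distribution-based routing
#'
#' Feature-versus-class group comparison, routed per the usual clinical
#' reporting convention: categorical features get a chi-squared
#' independence test (no continuity correction); continuous features
#' are first checked for normality per group with a Shapiro-Wilk test
#' at alpha = 0.05 — if every group passes, an unpaired two-tailed
#' t-test (two classes) or one-way ANOVA (more), otherwise Mann-Whitney
#' U respectively Kruskal-Wallis. Groups larger than 2000 route
#' non-parametric (the Shapiro-Wilk statistic is unreliable there).
#'
#' @param values per-subject feature values (numeric, or character for
#'   categorical features); missing values are excluded.
#' @param labels class labels.
#' @param kind `"continuous"`, `"binary"` or `"categorical"`.
#' @param alpha significance level, default 0.05.
#' @return list: `test` (one of t/mann-whitney/anova/kruskal-wallis/
#'   chi-squared/skipped), `p`, `statistic`, `significant`, `summary`
#'   (per-class mean/s.d. or level percentages), `reason` when skipped.
#' @export
featureHypothesisTest <- function(values, labels, kind, alpha = 0.05) {
  labels <- factor(labels)
  keep <- !is.na(values)
  values <- values[keep]
  g <- droplevels(labels[keep])
  counts <- table(g)
  if (length(counts) < 2 || any(counts < 3)) {
    return(list(
      test = "skipped", p = NA_real_, statistic = NA_real_,
      significant = NA, summary = NULL,
      reason = "needs >= 2 classes with >= 3 non-missing values each"
    ))
  }
  if (kind %in% c("binary", "categorical")) {
    tab <- table(g, values)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || ncol(tab) < 2) {
      return(list(
        test = "skipped", p = NA_real_, statistic = NA_real_,
        significant = NA, summary = NULL,
        reason = "degenerate contingency row/column"
      ))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    if (any(ct$expected < 5)) {
      warning("chi-squared with expected counts < 5; interpret with care")
    }
    summ <- prop.table(tab, margin = 1) * 100
    return(list(
      test = "chi-squared", p = unname(ct$p.value),
      statistic = unname(ct$statistic),
      significant = ct$p.value < alpha, summary = summ, reason = NA_character_
    ))
  }
  groups <- split(values, g)
  normal <- vapply(groups, function(v) {
    if (length(v) > 2000) return(FALSE)
    if (length(unique(v)) < 3) return(FALSE)
    shapiro.test(v)$p.value >= alpha
  }, logical(1))
  summ <- data.frame(
    class = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, sd, numeric(1)),
    row.names = NULL
  )
  if (length(groups) == 2) {
    if (all(normal)) {
      ht <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      test <- "t"
    } else {
      ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]], exact = FALSE))
      test <- "mann-whitney"
    }
  } else {
    if (all(normal)) {
      ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
      test <- "anova"
    } else {
      ht <- kruskal.test(values, g)
      test <- "kruskal-wallis"
    }
  }
  list(
    test = test, p = unname(ht$p.value), statistic = unname(ht$statistic),
    significant = ht$p.value < alpha, summary = summ, reason = NA_character_
  )
}

#' Hypothesis tests for the top-ranked features of a cohort
#'
#' Convenience wrapper running [featureHypothesisTest()] over a set of
#' source features of a [CohortTable], in the layout of a ranked
#' importance report table.
#'
#' @param table a [CohortTable].
#' @param features source feature names (defaults to all).
#' @param alpha significance level.
#' @return data.frame: feature, kind, test, p, significant.
#' @export
cohortFeatureTests <- function(table, features = NULL, alpha = 0.05) {
  feat <- schemaFeatures(table@schema)
  if (is.null(features)) features <- feat$name
  rows <- lapply(features, function(nm) {
    kind <- feat$kind[feat$name == nm]
    if (!length(kind)) {
      return(data.frame(
        feature = nm, kind = NA_character_, test = "skipped",
        p = NA_real_, significant = NA
      ))
    }
    res <- featureHypothesisTest(table@values[[nm]], table@labels, kind, alpha)
    data.frame(
      feature = nm, kind = kind, test = res$test, p = res$p,
      significant = res$significant
    )
  })
  do.call(rbind, rows)
}
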