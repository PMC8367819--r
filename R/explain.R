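#' Attribution settings
#'
#' @param baseline reference input for path attributions; `NULL` means
#'   the zero vector, which after z-transformation approximates the
#'   population-mean patient.
#' @param steps Riemann midpoints along the straight path (default 50).
#' @param nShuffles column shuffles for permutation importance.
#' @param seed integer seed for the permutation shuffles.
#' @return list of class `AttributionConfig`.
#' @export
attributionConfig <- function(baseline = NULL, steps = 50L, nShuffles = 5L,
                              seed = 1L) {
  if (steps < 1) stop("steps must be >= 1")
  structure(
    list(baseline = baseline, steps = as.integer(steps),
      nShuffles = as.integer(nShuffles), seed = as.integer(seed)),
    class = "AttributionConfig"
  )
}

#' Integrated Gradients attribution for one sample
#'
#' Path-integral attribution of a scalar score: feature i receives
#' `(x_i - baseline_i)` times the mean gradient of `predictFn` along the
#' straight path from the baseline to `x`, evaluated at `steps` Riemann
#' midpoints. As `steps` grows the attributions satisfy completeness:
#' they sum to `predictFn(x) - predictFn(baseline)`. For a linear score
#' the closed form `w * (x - baseline)` is recovered at any step count.
#'
#' @param predictFn function of a d-vector returning one differentiable
#'   score (e.g. the logit of one class).
#' @param x input d-vector.
#' @param cfg an [attributionConfig()].
#' @param gradFn optional analytic gradient function; the default is a
#'   central finite difference.
#' @return d-vector of attributions.
#' @export
integratedGradients <- function(predictFn, x, cfg = attributionConfig(),
                                gradFn = NULL) {
  d <- length(x)
  baseline <- if (is.null(cfg$baseline)) rep(0, d) else cfg$baseline
  diff <- x - baseline
  if (all(diff == 0)) return(rep(0, d))
  if (is.null(gradFn)) {
    gradFn <- function(z) {
      vapply(seq_len(d), function(j) {
        h <- 1e-5 * max(1, abs(z[j]))
        zp <- z; zm <- z
        zp[j] <- z[j] + h
        zm[j] <- z[j] - h
        (predictFn(zp) - predictFn(zm)) / (2 * h)
      }, numeric(1))
    }
  }
  total <- rep(0, d)
  for (t in seq_len(cfg$steps)) {
    alpha <- (t - 0.5) / cfg$steps
    g <- gradFn(baseline + alpha * diff)
    if (any(!is.finite(g))) stop("non-finite gradient along the attribution path")
    total <- total + g
  }
  diff * total / cfg$steps
}

# permutation importance: mean accuracy drop over nShuffles shuffles of
# each column (used for models without a native importance recipe)
permutationImportance <- function(model, X, y, cfg) {
  yChr <- as.character(y)
  acc <- function(M) {
    pred <- model@classes[max.col(predictProba(model, M), ties.method = "first")]
    mean(pred == yChr)
  }
  base <- acc(X)
  withSeed(childSeed(cfg$seed, "perm", model@spec@name), {
    vapply(seq_len(ncol(X)), function(j) {
      drops <- vapply(seq_len(cfg$nShuffles), function(s) {
        Xs <- X
        Xs[, j] <- X[sample.int(nrow(X)), j]
        base - acc(Xs)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
}

# mean Integrated Gradients attribution of the training samples toward
# their ground-truth class probability, batched over the Riemann path
mlpIGImportance <- function(model, X, y, cfg) {
  st <- model@state
  d <- ncol(X)
  baseline <- if (is.null(cfg$baseline)) rep(0, d) else cfg$baseline
  B <- matrix(baseline, nrow(X), d, byrow = TRUE)
  diff <- X - B
  target <- match(as.character(y), model@classes)
  gsum <- matrix(0, nrow(X), d)
  for (t in seq_len(cfg$steps)) {
    alpha <- (t - 0.5) / cfg$steps
    gsum <- gsum + mlpInputGrad(st, B + alpha * diff, target, score = "prob")
  }
  attr <- diff * gsum / cfg$steps
  colMeans(abs(attr))
}

# Integrated Gradients over the joint training score of the transductive
# model: the feature block is scaled toward the zero baseline jointly and
# the per-entry path integral is read off one batched backward per step
mgmcIGImportance <- function(model, cfg) {
  st <- model@state
  d <- st$d
  gsum <- matrix(0, nrow(st$M0), d)
  for (t in seq_len(cfg$steps)) {
    alpha <- (t - 0.5) / cfg$steps
    gsum <- gsum + mgmcFeatureGrad(st, alpha)
  }
  attr <- st$M0[, seq_len(d), drop = FALSE] * gsum / cfg$steps
  trainRows <- which(st$trainMask)
  colMeans(abs(attr[trainRows, , drop = FALSE]))
}

#' Per-model feature importance
#'
#' Family routing: linear models report the mean absolute coefficient
#' across one-vs-rest class rows; tree models (DT, RF, AB) their
#' impurity-decrease importances normalized to sum one; neural models
#' (MLP and the transductive graph model) the mean Integrated Gradients
#' attribution of every training sample toward its ground-truth class;
#' models without a native recipe (KNN, GP, GNB) fall back to seeded
#' permutation importance (mean accuracy drop over
#' `cfg$nShuffles` shuffles).
#'
#' @param model a [FittedModel].
#' @param X training design matrix (ignored by the transductive model,
#'   whose state already holds the cohort).
#' @param y training labels.
#' @param cfg an [attributionConfig()].
#' @return length-d numeric importance vector (non-negative except for
#'   permutation importances, which may dip below zero; RAFI takes
#'   absolute values).
#' @export
modelImportance <- function(model, X = NULL, y = NULL, cfg = attributionConfig()) {
  if (!is(model, "FittedModel")) stop("model must be a FittedModel")
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  name <- model@spec@name
  st <- model@state
  imp <- switch(name,
    LDA = colMeans(abs(t(st$fit$scaling))),
    LR = colMeans(abs(lrCoefMatrix(st))),
    SVC = colMeans(abs(svcCoefMatrix(st))),
    DT = {
      v <- numeric(st$d)
      vi <- st$fit$variable.importance
      if (!is.null(vi)) v[as.integer(sub("^V", "", names(vi)))] <- vi
      if (sum(v) > 0) v / sum(v) else v
    },
    RF = {
      v <- st$fit$variable.importance
      v <- v[vnames(st$d)]
      v[is.na(v)] <- 0
      if (sum(v) > 0) v / sum(v) else v
    },
    AB = {
      v <- abImportance(st)
      if (sum(v) > 0) v / sum(v) else v
    },
    MLP = mlpIGImportance(model, X, y, cfg),
    MGMC = mgmcIGImportance(model, cfg),
    KNN = ,
    GP = ,
    GNB = permutationImportance(model, X, y, cfg),
    stop(sprintf("no importance recipe for '%s'", name))
  )
  unname(as.numeric(imp))
}

#' RAFI: relative aggregation of feature importance
#'
#' Aggregates per-classifier importance vectors into one global ranking:
#' absolute values are taken (sign carries no rank information),
#' each classifier's row is normalized to sum one (percentual
#' importance, making scales comparable), and the normalized rows are
#' summed: `I0(phi_i) = sum_j |I_j(phi_i)| / sum_i' |I_j(phi_i')|`.
#' The total of `I0` equals the number of contributing classifiers.
#'
#' @param I F x d importance matrix (row per classifier, column per
#'   encoded feature); rownames and colnames are carried through.
#' @param origin optional length-d source-feature map; when given,
#'   one-hot columns of a shared source are pooled by summation before
#'   ranking, so the ranking names clinical variables rather than
#'   encoding columns.
#' @return an [AggregatedImportance].
#' @export
rafiAggregate <- function(I, origin = NULL) {
  I <- as.matrix(I)
  if (is.null(colnames(I))) colnames(I) <- paste0("f", seq_len(ncol(I)))
  if (is.null(rownames(I))) rownames(I) <- paste0("clf", seq_len(nrow(I)))
  A <- abs(I)
  sums <- rowSums(A)
  drop <- sums == 0
  if (any(drop)) {
    warning(sprintf(
      "classifier(s) %s have all-zero importances and are excluded",
      paste(rownames(I)[drop], collapse = ", ")
    ))
    A <- A[!drop, , drop = FALSE]
    sums <- sums[!drop]
  }
  if (nrow(A) == 0) stop("no classifier contributed a nonzero importance row")
  norm <- sweep(A, 1, sums, "/")
  if (!is.null(origin)) {
    stopifnot(length(origin) == ncol(norm))
    pooled <- t(rowsum(t(norm), group = origin, reorder = FALSE))
    norm <- pooled
  }
  I0 <- colSums(norm)
  ord <- order(-I0, seq_along(I0))
  new("AggregatedImportance",
    I0 = I0, ranking = colnames(norm)[ord], contributions = norm
  )
}

#' Top-k features of an aggregated importance
#'
#' @param agg an [AggregatedImportance].
#' @param k how many features (default 10, capped at d).
#' @return data.frame (rank, feature, I0) in descending importance; ties
#'   broken by feature index (stable).
#' @export
topFeatures <- function(agg, k = 10L) {
  k <- min(k, length(agg@ranking))
  feats <- agg@ranking[seq_len(k)]
  data.frame(rank = seq_len(k), feature = feats, I0 = unname(agg@I0[feats]))
}
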