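# Registry of classical classifiers behind the uniform fit / predictProba
# contract. Each trainer is seeded where stochastic; colnames are mapped to
# syntactic V-names for formula-based libraries and mapped back afterwards.

logUniform <- function(lo, hi) {
  force(lo); force(hi)
  function(n) exp(runif(n, log(lo), log(hi)))
}

#' The default model registry
#'
#' Returns the eleven classifier declarations used throughout: LDA
#' (default, no shrinkage), L2-penalized logistic regression, linear
#' support-vector classifier with squared-L2 penalty at cost 0.25,
#' Gaussian naive Bayes with priors estimated from the data, a Gaussian
#' process with zero-mean unit-variance RBF kernel refined during
#' fitting, 10-nearest-neighbors with Euclidean metric, a Gini decision
#' tree of maximum depth 5, a random forest of 10 depth-5 trees with
#' confidence-weighted voting, AdaBoost over decision stumps with up to
#' 50 estimators, an MLP with hidden layers (64, 32), dropout 0.3 and
#' batch normalization, and the transductive multi-graph geometric
#' matrix completion model (see [mgmcTrainPredict()]).
#'
#' Tunable parameters carry modest random-search spaces centered on the
#' stated defaults; LDA and GNB are fixed, the GP length-scale is fit
#' internally.
#'
#' @param names optional subset of model names to return.
#' @return named list of [ModelSpec] objects.
#' @export
defaultRegistry <- function(names = NULL) {
  specs <- list(
    LDA = new("ModelSpec",
      name = "LDA", family = "linear", transductive = FALSE,
      fixedParams = list(), defaultParams = list(), searchSpace = list()
    ),
    LR = new("ModelSpec",
      name = "LR", family = "linear", transductive = FALSE,
      fixedParams = list(penalty = "l2"),
      defaultParams = list(C = 1),
      searchSpace = list(C = logUniform(1e-3, 1e3))
    ),
    SVC = new("ModelSpec",
      name = "SVC", family = "linear", transductive = FALSE,
      fixedParams = list(kernel = "linear", penalty = "squared_l2"),
      defaultParams = list(cost = 0.25),
      searchSpace = list(cost = logUniform(1e-3, 1e3))
    ),
    GNB = new("ModelSpec",
      name = "GNB", family = "nonlinear", transductive = FALSE,
      fixedParams = list(priors = "from_data"),
      defaultParams = list(), searchSpace = list()
    ),
    GP = new("ModelSpec",
      name = "GP", family = "nonlinear", transductive = FALSE,
      fixedParams = list(kernel = "rbf", kernel_mean = 0, kernel_variance = 1),
      defaultParams = list(), searchSpace = list()
    ),
    KNN = new("ModelSpec",
      name = "KNN", family = "nonlinear", transductive = FALSE,
      fixedParams = list(metric = "euclidean"),
      defaultParams = list(k = 10L),
      searchSpace = list(k = c(3L, 5L, 10L, 15L, 25L))
    ),
    DT = new("ModelSpec",
      name = "DT", family = "nonlinear", transductive = FALSE,
      fixedParams = list(criterion = "gini"),
      defaultParams = list(max_depth = 5L),
      searchSpace = list(max_depth = c(3L, 5L, 8L, 12L))
    ),
    RF = new("ModelSpec",
      name = "RF", family = "nonlinear", transductive = FALSE,
      fixedParams = list(criterion = "gini", vote = "confidence_weighted"),
      defaultParams = list(n_trees = 10L, max_depth = 5L),
      searchSpace = list(
        n_trees = c(10L, 50L, 100L),
        max_depth = c(3L, 5L, 8L, 12L)
      )
    ),
    AB = new("ModelSpec",
      name = "AB", family = "nonlinear", transductive = FALSE,
      fixedParams = list(base = "stump"),
      defaultParams = list(n_estimators = 50L),
      searchSpace = list(n_estimators = c(10L, 25L, 50L))
    ),
    MLP = new("ModelSpec",
      name = "MLP", family = "neural", transductive = FALSE,
      fixedParams = list(
        hidden = c(64L, 32L), dropout = 0.3, batch_norm = TRUE,
        epochs = 200L, patience = 10L, tol = 1e-4
      ),
      defaultParams = list(learning_rate = 1e-3),
      searchSpace = list(learning_rate = logUniform(1e-4, 1e-2))
    ),
    MGMC = new("ModelSpec",
      name = "MGMC", family = "graph", transductive = TRUE,
      fixedParams = list(
        timesteps = 5L, cheb_order = 5L,
        gamma = 1e-3, lambda = 1, epochs = 500L, patience = 25L,
        learning_rate = 2e-2
      ),
      defaultParams = list(hidden = 32L),
      searchSpace = list(hidden = c(16L, 32L, 64L))
    )
  )
  if (!is.null(names)) {
    bad <- setdiff(names, base::names(specs))
    if (length(bad)) stop(sprintf("unknown model '%s'", bad[1]))
    specs <- specs[names]
  }
  specs
}

#' Merged default parametrization of a model
#'
#' @param spec a [ModelSpec].
#' @return named list of the fixed settings merged with the defaults of
#'   the tunable parameters — the registry's stated parametrization.
#' @export
modelDefaults <- function(spec) {
  c(spec@fixedParams, spec@defaultParams)
}

# sample one candidate setting from a search space (callers seed the RNG)
sampleSetting <- function(space) {
  lapply(space, function(s) {
    if (is.function(s)) s(1) else s[[sample.int(length(s), 1)]]
  })
}

vnames <- function(d) paste0("V", seq_len(d))

checkFitInputs <- function(X, y) {
  if (anyNA(X)) stop("design matrix may not contain missing entries")
  if (ncol(X) == 0) stop("design matrix needs at least one column")
  if (length(unique(as.character(y))) < 2) {
    stop("training labels must contain at least two classes")
  }
}

#' @rdname fitModel
#' @param params chosen hyperparameters overriding the defaults (as
#'   returned by [randomSearch()]).
setMethod("fitModel", "ModelSpec", function(spec, X, y, seed = 1L, params = list()) {
  p <- modifyList(modelDefaults(spec), params)
  if (spec@transductive) {
    return(fitMGMCModel(spec, X, y, seed = seed, params = p))
  }
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  y <- factor(as.character(y), levels = sort(unique(as.character(y))))
  checkFitInputs(X, y)
  state <- withSeed(childSeed(seed, "fit", spec@name), {
    switch(spec@name,
      LDA = fitLDA(X, y),
      LR = fitLR(X, y, p),
      SVC = fitSVC(X, y, p),
      GNB = fitGNB(X, y),
      GP = fitGP(X, y),
      KNN = fitKNNModel(X, y, p),
      DT = fitDT(X, y, p),
      RF = fitRF(X, y, p, childSeed(seed, "ranger", spec@name)),
      AB = fitAB(X, y, p),
      MLP = fitMLPModel(X, y, p, childSeed(seed, "mlp")),
      stop(sprintf("unknown model '%s'", spec@name))
    )
  })
  spec2 <- spec
  spec2@defaultParams <- p[names(p) %in% c(names(spec@defaultParams), names(spec@searchSpace))]
  new("FittedModel",
    spec = spec2, state = state,
    classes = levels(y), trainDim = ncol(X)
  )
})

#' @rdname predictProba
setMethod("predictProba", "FittedModel", function(model, X) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  if (model@spec@transductive) {
    return(predictMGMCModel(model, X))
  }
  if (ncol(X) != model@trainDim) {
    stop(sprintf("expected %d columns, got %d", model@trainDim, ncol(X)))
  }
  st <- model@state
  probs <- switch(model@spec@name,
    LDA = predict(st$fit, X)$posterior,
    LR = predictLR(st, X),
    SVC = predictSVC(st, X),
    GNB = predictGNB(st, X),
    GP = {
      pr <- kernlab::predict(st$fit, X, type = "probabilities")
      pr[, model@classes, drop = FALSE]
    },
    KNN = predictKNN(st, X),
    DT = {
      df <- as.data.frame(X)
      names(df) <- vnames(ncol(X))
      predict(st$fit, df, type = "prob")
    },
    RF = {
      pr <- predict(st$fit, data = asVDF(X))$predictions
      pr[, model@classes, drop = FALSE]
    },
    AB = predictAB(st, X),
    MLP = mlpPredictProba(st, X),
    stop("unknown model")
  )
  probs <- as.matrix(probs)[, model@classes, drop = FALSE]
  probs <- probs / rowSums(probs)
  stopifnotProb(probs)
  probs
})

asVDF <- function(X) {
  df <- as.data.frame(X)
  names(df) <- vnames(ncol(X))
  df
}

## ---- individual trainers -------------------------------------------------

fitLDA <- function(X, y) {
  list(fit = MASS::lda(x = X, grouping = y))
}

# one-vs-rest ridge logistic regression; lambda = 1/(n C) maps the
# regularization strength C onto glmnet's per-observation scaling
fitLR <- function(X, y, p) {
  n <- nrow(X)
  lambda <- 1 / (n * p$C)
  Xg <- if (ncol(X) == 1) cbind(X, 0) else X
  classes <- levels(y)
  targets <- if (length(classes) == 2) classes[2] else classes
  fits <- lapply(targets, function(cl) {
    glmnet::glmnet(Xg, factor(y == cl, levels = c(FALSE, TRUE)),
      family = "binomial", alpha = 0, lambda = lambda, standardize = FALSE
    )
  })
  names(fits) <- targets
  list(fits = fits, classes = classes, padded = ncol(X) == 1)
}

predictLR <- function(st, X) {
  Xg <- if (st$padded) cbind(X, 0) else X
  scores <- vapply(st$fits, function(f) {
    as.numeric(predict(f, Xg, type = "response"))
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  if (length(st$classes) == 2) {
    probs <- cbind(1 - scores[, 1], scores[, 1])
  } else {
    probs <- scores / rowSums(scores)
  }
  colnames(probs) <- st$classes
  probs
}

lrCoefMatrix <- function(st) {
  co <- vapply(st$fits, function(f) as.numeric(coef(f))[-1], numeric(
    length(as.numeric(coef(st$fits[[1]]))) - 1
  ))
  co <- matrix(co, ncol = length(st$fits))
  if (st$padded) co <- co[1, , drop = FALSE]
  t(co) # classes x d
}

# linear SVC with logistic calibration of the signed margin (fitted on the
# training data); one-vs-rest for multi-class
fitSVC <- function(X, y, p) {
  classes <- levels(y)
  targets <- if (length(classes) == 2) classes[2] else classes
  fits <- lapply(targets, function(cl) {
    ybin <- factor(y == cl, levels = c(FALSE, TRUE))
    m <- e1071::svm(X, ybin, type = "C-classification",
      kernel = "linear", cost = p$cost, scale = FALSE
    )
    w <- crossprod(m$coefs, m$SV) # 1 x d
    dv <- as.numeric(X %*% t(w)) - m$rho
    cal <- suppressWarnings(glm((y == cl) ~ dv, family = binomial()))
    list(w = w, rho = m$rho, cal = coef(cal))
  })
  names(fits) <- targets
  list(fits = fits, classes = classes)
}

predictSVC <- function(st, X) {
  scores <- vapply(st$fits, function(f) {
    dv <- as.numeric(X %*% t(f$w)) - f$rho
    plogis(f$cal[1] + f$cal[2] * dv)
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  if (length(st$classes) == 2) {
    probs <- cbind(1 - scores[, 1], scores[, 1])
  } else {
    probs <- scores / rowSums(scores)
  }
  colnames(probs) <- st$classes
  probs
}

svcCoefMatrix <- function(st) {
  t(vapply(st$fits, function(f) as.numeric(f$w), numeric(length(f <- st$fits[[1]]$w))))
}

# Gaussian naive Bayes with class priors estimated from the data and a
# small variance floor (1e-9 of the largest feature variance) so that
# zero-variance one-hot columns stay numerically benign. Vectorized:
# log-densities of all samples and classes come from matrix algebra.
fitGNB <- function(X, y) {
  classes <- levels(y)
  mu <- t(matrix(vapply(classes, function(cl) {
    colMeans(X[y == cl, , drop = FALSE])
  }, numeric(ncol(X))), ncol(X), length(classes)))
  v <- t(matrix(vapply(classes, function(cl) {
    xs <- X[y == cl, , drop = FALSE]
    colMeans(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(ncol(X))), ncol(X), length(classes)))
  v <- v + 1e-9 * max(apply(X, 2, function(col) mean((col - mean(col))^2)), 1e-12)
  prior <- as.numeric(table(y)[classes]) / length(y)
  list(mu = mu, v = v, logPrior = log(prior), classes = classes)
}

predictGNB <- function(st, X) {
  n <- nrow(X)
  ll <- vapply(seq_along(st$classes), function(ci) {
    mu <- st$mu[ci, ]
    v <- st$v[ci, ]
    centered2 <- sweep(X, 2, mu)^2
    rep(-0.5 * sum(log(2 * pi * v)), n) - 0.5 * as.numeric(centered2 %*% (1 / v))
  }, numeric(n))
  ll <- matrix(ll, nrow = n) + matrix(st$logPrior, n, length(st$classes), byrow = TRUE)
  P <- softmaxRows(ll)
  colnames(P) <- st$classes
  P
}

fitGP <- function(X, y) {
  # kernlab chats about the sigma heuristic on stdout; keep fits quiet
  msg <- utils::capture.output(
    fit <- suppressMessages(
      kernlab::gausspr(X, y, kernel = "rbfdot", kpar = "automatic")
    )
  )
  list(fit = fit)
}

fitKNNModel <- function(X, y, p) {
  list(X = X, y = y, k = min(p$k, nrow(X)))
}

# neighbor-vote class probabilities under the Euclidean metric; ties in
# distance broken by row order (deterministic)
predictKNN <- function(st, X) {
  classes <- levels(st$y)
  d2 <- outer(rowSums(X^2), rep(1, nrow(st$X))) +
    outer(rep(1, nrow(X)), rowSums(st$X^2)) - 2 * X %*% t(st$X)
  probs <- t(apply(d2, 1, function(row) {
    nb <- order(row)[seq_len(st$k)]
    tabulate(as.integer(st$y[nb]), nbins = length(classes)) / st$k
  }))
  colnames(probs) <- classes
  probs
}

fitDT <- function(X, y, p) {
  df <- asVDF(X)
  df$.y <- y
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(
      maxdepth = p$max_depth, cp = 0, xval = 0, minsplit = 2,
      minbucket = 1, maxsurrogate = 0, maxcompete = 0
    )
  )
  list(fit = fit, d = ncol(X))
}

fitRF <- function(X, y, p, seed) {
  fit <- ranger::ranger(
    x = asVDF(X), y = y, num.trees = p$n_trees, max.depth = p$max_depth,
    probability = TRUE, importance = "impurity", seed = seed,
    num.threads = 1
  )
  list(fit = fit, d = ncol(X))
}

# multi-class AdaBoost (SAMME) over depth-1 rpart stumps
fitAB <- function(X, y, p) {
  n <- nrow(X)
  C <- nlevels(y)
  df <- asVDF(X)
  df$.y <- y
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric()
  for (t in seq_len(p$n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, method = "class", weights = w * n,
      parms = list(split = "gini"),
      control = rpart::rpart.control(
        maxdepth = 1, cp = 0, xval = 0, minsplit = 2, minbucket = 1,
        maxsurrogate = 0, maxcompete = 0
      )
    )
    pred <- predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w * miss)
    if (err <= 0) {
      stumps[[length(stumps) + 1]] <- fit
      alphas <- c(alphas, log(1e10) + log(C - 1))
      break
    }
    if (err >= 1 - 1 / C) {
      if (length(stumps) == 0) {
        stumps[[1]] <- fit
        alphas <- 1
      }
      break
    }
    a <- log((1 - err) / err) + log(C - 1)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, a)
    w <- w * exp(a * miss)
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, classes = levels(y), d = ncol(X))
}

predictAB <- function(st, X) {
  df <- asVDF(X)
  scores <- matrix(0, nrow(X), length(st$classes),
    dimnames = list(NULL, st$classes)
  )
  for (t in seq_along(st$stumps)) {
    pred <- predict(st$stumps[[t]], df, type = "class")
    scores[cbind(seq_len(nrow(X)), as.integer(pred))] <-
      scores[cbind(seq_len(nrow(X)), as.integer(pred))] + st$alphas[t]
  }
  tot <- rowSums(scores)
  probs <- scores / ifelse(tot > 0, tot, 1)
  probs[tot == 0, ] <- 1 / length(st$classes)
  probs
}

abImportance <- function(st) {
  imp <- numeric(st$d)
  for (t in seq_along(st$stumps)) {
    vi <- st$stumps[[t]]$variable.importance
    if (is.null(vi)) next
    idx <- as.integer(sub("^V", "", names(vi)))
    imp[idx] <- imp[idx] + st$alphas[t] * vi
  }
  imp
}
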