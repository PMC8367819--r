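# Transductive multi-graph geometric matrix completion (MGMC).
#
# The cohort is modelled as nodes of several patient graphs, one per
# meta feature (same gender; age within +/- 6 years; EQ5D within
# +/- 0.06; DHI within +/- 11). Features and one-hot labels form one
# completion matrix whose observed entries are the non-missing cells
# plus the training labels. A recurrent graph convolutional network —
# Chebyshev spectral filters over every graph, summed, a single hidden
# layer, and a gated (input/forget) recurrent update of the completion —
# minimizes reconstruction error on observed entries, graph smoothness,
# and cross-entropy on training rows, yielding imputations and class
# probabilities for all rows at once.

#' Default meta-feature graph rules
#'
#' @return data.frame of rules: same gender; age difference within 6
#'   years; EQ5D score difference within 0.06; DHI score difference
#'   within 11.
#' @export
defaultGraphRules <- function() {
  data.frame(
    meta = c("gender", "age", "eq5d", "dhi"),
    type = c("equal", "abs_diff", "abs_diff", "abs_diff"),
    threshold = c(NA, 6, 0.06, 11),
    stringsAsFactors = FALSE
  )
}

#' Build per-meta-feature patient graphs
#'
#' For numeric rules an edge joins subjects i != j when
#' `|meta(i) - meta(j)| <= threshold`; for equality rules when the two
#' values are equal. Pairs with a missing value on either side get no
#' edge.
#'
#' @param meta data.frame with one row per subject holding the meta
#'   columns named by the rules.
#' @param rules data.frame with columns `meta`, `type`
#'   (`"equal"`/`"abs_diff"`) and `threshold`; see [defaultGraphRules()].
#' @return a [MetaGraphSet].
#' @export
buildMetaGraphs <- function(meta, rules = defaultGraphRules()) {
  absent <- setdiff(rules$meta, names(meta))
  if (length(absent)) {
    stop(sprintf("graph rule names absent column '%s'", absent[1]))
  }
  if (any(!is.na(rules$threshold) & rules$threshold < 0)) {
    stop("thresholds must be nonnegative")
  }
  n <- nrow(meta)
  graphs <- lapply(seq_len(nrow(rules)), function(r) {
    v <- meta[[rules$meta[r]]]
    if (rules$type[r] == "equal") {
      A <- outer(v, v, function(a, b) as.numeric(a == b))
    } else {
      v <- as.numeric(v)
      A <- outer(v, v, function(a, b) as.numeric(abs(a - b) <= rules$threshold[r]))
    }
    A[is.na(A)] <- 0
    diag(A) <- 0
    unname(A)
  })
  new("MetaGraphSet", graphs = graphs, rules = rules)
}

#' Edge list of a MetaGraphSet
#'
#' @param graphs a [MetaGraphSet].
#' @return data.frame (graph, i, j) with i < j, for inspection/export.
#' @export
graphEdgeList <- function(graphs) {
  rows <- lapply(seq_along(graphs@graphs), function(g) {
    idx <- which(upper.tri(graphs@graphs[[g]]) & graphs@graphs[[g]] == 1, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      return(data.frame(graph = character(), i = integer(), j = integer()))
    }
    data.frame(graph = graphs@rules$meta[g], i = idx[, 1], j = idx[, 2])
  })
  do.call(rbind, rows)
}

# symmetric normalized Laplacian with the zero-row convention for
# isolated nodes
normLaplacian <- function(A) {
  deg <- rowSums(A)
  n <- nrow(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- -A * outer(dinv, dinv)
  diag(L) <- as.numeric(deg > 0)
  L
}

laplacianLambdaMax <- function(L, powerSteps = 50) {
  n <- nrow(L)
  if (n <= 2000) {
    mx <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  } else {
    # power iteration; deterministic ramp start avoids orthogonal starts
    v <- seq_len(n) / n
    v <- v / sqrt(sum(v^2))
    for (s in seq_len(powerSteps)) {
      w <- L %*% v
      nw <- sqrt(sum(w^2))
      if (nw == 0) return(0)
      v <- as.numeric(w) / nw
    }
    mx <- as.numeric(crossprod(v, L %*% v))
  }
  mx
}

#' Scaled graph Laplacian for Chebyshev filtering
#'
#' Computes `L~ = 2 L_sym / lambda_max - I` with
#' `L_sym = I - D^(-1/2) A D^(-1/2)`; rows of isolated nodes are zero in
#' `L_sym` (so an empty graph yields `L~ = -I`). Eigenvalues of the
#' result lie in `[-1, 1]`, the domain on which Chebyshev polynomials
#' form a stable basis.
#'
#' @param A symmetric 0/1 adjacency matrix with zero diagonal.
#' @return N x N scaled Laplacian matrix.
#' @export
scaledLaplacian <- function(A) {
  if (!isSymmetric(unname(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  L <- normLaplacian(A)
  lmax <- laplacianLambdaMax(L)
  if (lmax <= 0) lmax <- 2
  2 * L / lmax - diag(nrow(A))
}

#' Chebyshev spectral filter stack
#'
#' Returns the horizontal concatenation `[T_0(L~) X, ..., T_{K-1}(L~) X]`
#' under the recurrence `T_0 = I`, `T_1 = L~`,
#' `T_k = 2 L~ T_{k-1} - T_{k-2}`.
#'
#' @param Lt scaled Laplacian from [scaledLaplacian()].
#' @param X N x d feature block.
#' @param order polynomial order K >= 1.
#' @return N x (K d) matrix.
#' @export
chebyshevFilter <- function(Lt, X, order) {
  if (order < 1) stop("order must be >= 1")
  if (nrow(X) != nrow(Lt)) stop("dimension mismatch between Laplacian and features")
  blocks <- vector("list", order)
  blocks[[1]] <- X
  if (order >= 2) blocks[[2]] <- Lt %*% X
  if (order >= 3) {
    for (k in 3:order) {
      blocks[[k]] <- 2 * (Lt %*% blocks[[k - 1]]) - blocks[[k - 2]]
    }
  }
  do.call(cbind, blocks)
}

#' Precompute the graph filtering basis
#'
#' Scaled Laplacians, their summed Chebyshev powers and the summed
#' normalized Laplacian for the smoothness term, computed once per
#' subject set; [mgmcTrainPredict()] accepts the result so repeated fits
#' on the same rows (hyperparameter search) skip the setup.
#'
#' @param graphs a [MetaGraphSet].
#' @param chebOrder Chebyshev polynomial order.
#' @return list with `Astack`, `G`, `Lsum`.
#' @export
mgmcBasis <- function(graphs, chebOrder = 5L) {
  Lts <- lapply(graphs@graphs, scaledLaplacian)
  Ak <- chebBasisSum(Lts, chebOrder)
  list(
    Astack = stackBasis(Ak),
    G = length(Lts),
    Lsum = Reduce(`+`, lapply(graphs@graphs, normLaplacian))
  )
}

# Sum_g T_k(L~_g) precomputed once per fit; k = 0 contributes G * I and is
# handled as a scalar. Mathematically identical to filtering each graph
# separately and summing (the aggregation is linear).
chebBasisSum <- function(Lts, order) {
  n <- nrow(Lts[[1]])
  Ak <- vector("list", order)
  for (g in seq_along(Lts)) {
    Tm2 <- diag(n)
    Tm1 <- Lts[[g]]
    if (order >= 2) {
      Ak[[2]] <- if (is.null(Ak[[2]])) Tm1 else Ak[[2]] + Tm1
    }
    if (order >= 3) {
      for (k in 3:order) {
        Tk <- 2 * (Lts[[g]] %*% Tm1) - Tm2
        Ak[[k]] <- if (is.null(Ak[[k]])) Tk else Ak[[k]] + Tk
        Tm2 <- Tm1
        Tm1 <- Tk
      }
    }
  }
  Ak
}

#' MGMC hyperparameters
#'
#' @param timesteps recurrent refinement iterations (default 5).
#' @param chebOrder Chebyshev polynomial order (default 5).
#' @param hidden neurons in the single hidden layer before the output;
#'   16, 32 or 64 depending on the task (default 32).
#' @param reconWeight,gamma,lambda loss weights of the reconstruction,
#'   graph-smoothness and classification terms (defaults 1, 1e-3, 1).
#' @param epochs,learningRate,patience,tol Adam schedule: up to 500
#'   epochs at rate 0.02, stopping once the mean per-epoch improvement
#'   of the total loss over the last `patience` epochs falls below
#'   `tol` (training-loss plateau).
#' @param seed integer seed for the weight initialization.
#' @return list of class `MGMCConfig`.
#' @export
mgmcConfig <- function(timesteps = 5L, chebOrder = 5L, hidden = 32L,
                       reconWeight = 1, gamma = 1e-3, lambda = 1,
                       epochs = 500L, learningRate = 2e-2,
                       patience = 25L, tol = 2e-4, seed = 1L) {
  stopifnot(timesteps >= 1, chebOrder >= 1,
    reconWeight >= 0, gamma >= 0, lambda >= 0)
  structure(
    list(
      timesteps = as.integer(timesteps), chebOrder = as.integer(chebOrder),
      hidden = as.integer(hidden), reconWeight = reconWeight,
      gamma = gamma, lambda = lambda, epochs = as.integer(epochs),
      learningRate = learningRate, patience = as.integer(patience),
      tol = tol, seed = as.integer(seed)
    ),
    class = "MGMCConfig"
  )
}

mgmcInitParams <- function(Fin, K, h, C) {
  list(
    W1 = matrix(rnorm(K * Fin * h, sd = sqrt(2 / (K * Fin))), K * Fin, h),
    b1 = rep(0, h),
    Wf = matrix(rnorm(h * Fin, sd = sqrt(1 / h)), h, Fin),
    bf = rep(1, Fin), # forget bias: start near the identity update
    Wi = matrix(rnorm(h * Fin, sd = sqrt(1 / h)), h, Fin),
    bi = rep(0, Fin),
    Wc = matrix(rnorm(h * Fin, sd = sqrt(1 / h)), h, Fin),
    bc = rep(0, Fin)
  )
}

# one forward pass through the recurrent refinement; caches per timestep
mgmcForward <- function(params, M0, Astack, G, T, cache = FALSE) {
  M <- M0
  caches <- if (cache) vector("list", T) else NULL
  for (t in seq_len(T)) {
    Z <- mgmcZ(M, Astack, G)
    Hpre <- addCols(Z %*% params$W1, params$b1)
    H <- pmax(Hpre, 0)
    f <- sigmoid(addCols(H %*% params$Wf, params$bf))
    i <- sigmoid(addCols(H %*% params$Wi, params$bi))
    cc <- tanh(addCols(H %*% params$Wc, params$bc))
    Mout <- f * M + i * cc
    if (cache) {
      caches[[t]] <- list(Min = M, Z = Z, Hpre = Hpre, H = H, f = f, i = i, cc = cc)
    }
    M <- Mout
  }
  list(M = M, caches = caches)
}

# stacked [A_1; ...; A_{K-1}] so all Chebyshev blocks come from one GEMM;
# order 1 keeps only the identity block, giving an empty stack
stackBasis <- function(Ak) {
  if (length(Ak) < 2) return(NULL)
  do.call(rbind, Ak[-1])
}

mgmcZ <- function(M, Astack, G) {
  if (is.null(Astack)) return(G * M)
  n <- nrow(M)
  S <- Astack %*% M
  K <- nrow(Astack) / n + 1
  Z <- matrix(0, n, K * ncol(M))
  Z[, seq_len(ncol(M))] <- G * M
  for (k in 2:K) {
    Z[, (k - 1) * ncol(M) + seq_len(ncol(M))] <- S[(k - 2) * n + seq_len(n), ]
  }
  Z
}

# backward through the recurrence; dM is the loss gradient at the final
# completion. Returns parameter gradients and the gradient at M0.
# Adjoint of the filter stack: the A_k are symmetric, so
# dM += G dZ_0 + sum_k A_k dZ_k is one GEMM with the same stacked basis.
mgmcBackward <- function(params, caches, dM, Astack, G) {
  n <- nrow(dM)
  K <- if (is.null(Astack)) 1 else nrow(Astack) / n + 1
  Fin <- ncol(dM)
  grads <- lapply(params, function(x) x * 0)
  for (t in rev(seq_along(caches))) {
    cc <- caches[[t]]
    df <- dM * cc$Min
    di <- dM * cc$cc
    dc <- dM * cc$i
    dMin <- dM * cc$f
    daf <- df * cc$f * (1 - cc$f)
    dai <- di * cc$i * (1 - cc$i)
    dac <- dc * (1 - cc$cc^2)
    grads$Wf <- grads$Wf + crossprod(cc$H, daf)
    grads$bf <- grads$bf + colSums(daf)
    grads$Wi <- grads$Wi + crossprod(cc$H, dai)
    grads$bi <- grads$bi + colSums(dai)
    grads$Wc <- grads$Wc + crossprod(cc$H, dac)
    grads$bc <- grads$bc + colSums(dac)
    dH <- daf %*% t(params$Wf) + dai %*% t(params$Wi) + dac %*% t(params$Wc)
    dHpre <- dH * (cc$Hpre > 0)
    grads$W1 <- grads$W1 + crossprod(cc$Z, dHpre)
    grads$b1 <- grads$b1 + colSums(dHpre)
    dZ <- dHpre %*% t(params$W1)
    dMin <- dMin + G * dZ[, seq_len(Fin), drop = FALSE]
    if (K > 1) {
      dZstack <- matrix(0, (K - 1) * n, Fin)
      for (k in 2:K) {
        dZstack[(k - 2) * n + seq_len(n), ] <-
          dZ[, (k - 1) * Fin + seq_len(Fin), drop = FALSE]
      }
      dMin <- dMin + crossprod(Astack, dZstack)
    }
    dM <- dMin
  }
  list(grads = grads, dM0 = dM)
}

#' Train the transductive completion model and predict all rows
#'
#' Minimizes a composite loss: squared reconstruction error on the
#' observed feature entries, graph smoothness
#' `gamma * sum_g tr(M' L_g M)` over the meta graphs, and cross-entropy
#' on the training rows (classification-as-completion: one-hot label
#' columns observed only at training rows). Labels of non-training rows
#' never enter the loss; the model nevertheless produces a probability
#' row for every subject.
#'
#' @param X N x d numeric matrix, `NA` at unobserved entries (the raw,
#'   un-imputed representation; z-scored features recommended).
#' @param y length-N class labels; entries outside `trainMask` are
#'   ignored (may be `NA`).
#' @param graphs a [MetaGraphSet] over the same N subjects.
#' @param trainMask logical length N, TRUE where the label is observed.
#' @param cfg an [mgmcConfig()].
#' @param classes optional class order; default sorted unique training
#'   labels.
#' @param basis optional precomputed graph basis from [mgmcBasis()];
#'   reusable across fits on the same rows (e.g. the inner folds of a
#'   hyperparameter search).
#' @return list: `Xhat` (completed feature matrix), `P` (N x C
#'   probability matrix, all rows), `observedMask`, `trainMask`,
#'   `classes`, `loss` (per-epoch total loss), and the fitted internals
#'   (`params`, `Astack`, `M0`, `d`) used for attributions.
#' @export
mgmcTrainPredict <- function(X, y, graphs, trainMask, cfg = mgmcConfig(),
                             classes = NULL, basis = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  obs <- !is.na(X)
  if (!any(obs)) stop("no observed entries in the feature matrix")
  if (length(graphs@graphs) < 1) stop("at least one graph is required")
  yTrain <- as.character(y[trainMask])
  if (length(unique(yTrain)) < 2) stop("need >= 2 classes among training labels")
  if (is.null(classes)) classes <- sort(unique(yTrain))
  C <- length(classes)
  if (all(vapply(graphs@graphs, function(g) sum(g) == 0, logical(1)))) {
    warning("all graphs are edgeless; the model degrades to a per-row network")
  }

  if (is.null(basis)) basis <- mgmcBasis(graphs, cfg$chebOrder)
  Astack <- basis$Astack
  G <- basis$G
  Lsum <- basis$Lsum

  X0 <- X
  X0[!obs] <- 0
  Y <- matrix(0, n, C)
  yiTrain <- match(as.character(y), classes)
  trainRows <- which(trainMask)
  Y[cbind(trainRows, yiTrain[trainRows])] <- 1
  M0 <- cbind(X0, Y)
  Fin <- d + C
  nObs <- sum(obs)
  nTrain <- length(trainRows)

  withSeed(childSeed(cfg$seed, "mgmc"), {
    params <- mgmcInitParams(Fin, cfg$chebOrder, cfg$hidden, C)
    adam <- list(
      m = lapply(params, function(x) x * 0),
      v = lapply(params, function(x) x * 0)
    )
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lossHist <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      fw <- mgmcForward(params, M0, Astack, G, cfg$timesteps, cache = TRUE)
      M <- fw$M
      Mx <- M[, seq_len(d), drop = FALSE]
      logits <- M[, d + seq_len(C), drop = FALSE]
      P <- softmaxRows(logits)
      resid <- (Mx - X0) * obs
      lossRecon <- sum(resid^2) / nObs
      LsumM <- Lsum %*% M
      lossSmooth <- sum(M * LsumM) / (n * Fin)
      ceRows <- -log(pmax(P[cbind(trainRows, yiTrain[trainRows])], 1e-12))
      lossClass <- mean(ceRows)
      loss <- cfg$reconWeight * lossRecon + cfg$gamma * lossSmooth +
        cfg$lambda * lossClass
      lossHist[epoch] <- loss

      dM <- matrix(0, n, Fin)
      dM[, seq_len(d)] <- cfg$reconWeight * 2 * resid / nObs
      # d/dlogits of mean CE over train rows: (P - Y)/nTrain at train rows
      dLogits <- matrix(0, n, C)
      dLogits[trainRows, ] <- (P[trainRows, , drop = FALSE] -
        Y[trainRows, , drop = FALSE]) / nTrain
      dM[, d + seq_len(C)] <- dM[, d + seq_len(C)] + cfg$lambda * dLogits
      dM <- dM + cfg$gamma * 2 * LsumM / (n * Fin)

      bw <- mgmcBackward(params, fw$caches, dM, Astack, G)
      for (nm in names(params)) {
        g <- bw$grads[[nm]]
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g^2
        mhat <- adam$m[[nm]] / (1 - b1^epoch)
        vhat <- adam$v[[nm]] / (1 - b2^epoch)
        params[[nm]] <- params[[nm]] - cfg$learningRate * mhat / (sqrt(vhat) + eps)
      }
      # plateau rule: stop once the mean per-epoch improvement over the
      # last `patience` epochs falls below `tol`
      if (epoch > cfg$patience &&
          (lossHist[epoch - cfg$patience] - loss) < cfg$tol * cfg$patience) {
        break
      }
    }
    lossHist <- lossHist[seq_len(epoch)]
    fw <- mgmcForward(params, M0, Astack, G, cfg$timesteps)
    M <- fw$M
    Xhat <- M[, seq_len(d), drop = FALSE]
    # observed cells are kept verbatim in the completed output
    Xhat[obs] <- X[obs]
    P <- softmaxRows(M[, d + seq_len(C), drop = FALSE])
    colnames(P) <- classes
    list(
      Xhat = Xhat, P = P, Mx = M[, seq_len(d), drop = FALSE],
      observedMask = obs, trainMask = trainMask, classes = classes,
      loss = lossHist, params = params, Astack = Astack, G = G, M0 = M0, d = d,
      timesteps = cfg$timesteps, cfg = cfg
    )
  })
}

# gradient of the summed true-class probabilities of the training rows
# with respect to the initial feature block; used by Integrated
# Gradients. alpha scales the feature block along the straight path from
# the zero baseline.
mgmcFeatureGrad <- function(state, alpha = 1) {
  d <- state$d
  M0 <- state$M0
  M0[, seq_len(d)] <- alpha * M0[, seq_len(d)]
  fw <- mgmcForward(state$params, M0, state$Astack, state$G, state$timesteps, cache = TRUE)
  n <- nrow(M0)
  C <- length(state$classes)
  dM <- matrix(0, n, ncol(M0))
  trainRows <- which(state$trainMask)
  lab <- max.col(state$M0[trainRows, d + seq_len(C), drop = FALSE])
  # softmax jacobian row of each training row's true-class probability
  P <- softmaxRows(fw$M[trainRows, d + seq_len(C), drop = FALSE])
  pt <- P[cbind(seq_along(trainRows), lab)]
  dL <- -P * pt
  dL[cbind(seq_along(trainRows), lab)] <- pt * (1 - pt)
  dM[trainRows, d + seq_len(C)] <- dL
  bw <- mgmcBackward(state$params, fw$caches, dM, state$Astack, state$G)
  bw$dM0[, seq_len(d), drop = FALSE]
}

mgmcTrainScore <- function(state, alpha = 1) {
  d <- state$d
  M0 <- state$M0
  M0[, seq_len(d)] <- alpha * M0[, seq_len(d)]
  fw <- mgmcForward(state$params, M0, state$Astack, state$G, state$timesteps)
  C <- length(state$classes)
  trainRows <- which(state$trainMask)
  lab <- max.col(state$M0[trainRows, d + seq_len(C), drop = FALSE])
  P <- softmaxRows(fw$M[trainRows, d + seq_len(C), drop = FALSE])
  sum(P[cbind(seq_along(trainRows), lab)])
}

## ---- registry glue ---------------------------------------------------------

# transductive fit: X is a list(X = full N x d matrix with NA, graphs =
# MetaGraphSet, trainIdx = integer rows whose labels are observed);
# y holds the labels of all N rows (non-train entries ignored).
fitMGMCModel <- function(spec, X, y, seed = 1L, params = list()) {
  stopifnot(is.list(X), !is.null(X$X), !is.null(X$graphs), !is.null(X$trainIdx))
  n <- nrow(X$X)
  trainMask <- rep(FALSE, n)
  trainMask[X$trainIdx] <- TRUE
  classes <- sort(unique(as.character(y[trainMask])))
  cfg <- mgmcConfig(
    timesteps = params$timesteps, chebOrder = params$cheb_order,
    hidden = params$hidden, gamma = params$gamma, lambda = params$lambda,
    epochs = params$epochs, learningRate = params$learning_rate,
    patience = params$patience, seed = childSeed(seed, "mgmcfit")
  )
  state <- mgmcTrainPredict(X$X, y, X$graphs, trainMask, cfg,
    classes = classes, basis = X$basis)
  spec2 <- spec
  spec2@defaultParams <- params[names(params) %in% c(names(spec@defaultParams), names(spec@searchSpace))]
  new("FittedModel",
    spec = spec2, state = state, classes = classes,
    trainDim = ncol(X$X)
  )
}

# transductive predictions are read off the completion state; X selects rows
predictMGMCModel <- function(model, X) {
  idx <- if (is.list(X)) X$idx else as.integer(X)
  P <- model@state$P[idx, , drop = FALSE]
  stopifnotProb(P)
  P
}
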