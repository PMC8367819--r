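# Fully-connected classifier: two hidden layers (64, 32), each
# linear -> ReLU -> dropout(0.3) -> batch normalization, then a linear
# softmax head. Trained full-batch with cross-entropy and Adam; early
# stop on a training-loss plateau. Written with explicit forward /
# backward passes so the same code yields analytic input gradients for
# Integrated Gradients attributions.

mlpInit <- function(d, hidden, C) {
  dims <- c(d, hidden, C)
  params <- list()
  for (l in seq_len(length(dims) - 1)) {
    fanIn <- dims[l]
    params[[l]] <- list(
      W = matrix(rnorm(fanIn * dims[l + 1], sd = sqrt(2 / fanIn)), fanIn, dims[l + 1]),
      b = rep(0, dims[l + 1])
    )
    if (l <= length(hidden)) {
      params[[l]]$gamma <- rep(1, dims[l + 1])
      params[[l]]$beta <- rep(0, dims[l + 1])
    }
  }
  params
}

BN_EPS <- 1e-5

# forward through one hidden block; training mode applies dropout and
# batch statistics, eval mode uses running statistics
mlpBlockForward <- function(X, layer, dropout, training, running, cache = FALSE) {
  a <- addCols(X %*% layer$W, layer$b)
  h <- pmax(a, 0)
  if (training && dropout > 0) {
    mask <- matrix(runif(length(h)) >= dropout, nrow(h), ncol(h))
    hd <- h * mask / (1 - dropout)
  } else {
    mask <- NULL
    hd <- h
  }
  if (training) {
    mu <- colMeans(hd)
    v <- colMeans(subCols(hd, mu)^2)
  } else {
    mu <- running$mean
    v <- running$var
  }
  xhat <- divCols(subCols(hd, mu), sqrt(v + BN_EPS))
  out <- addCols(mulCols(xhat, layer$gamma), layer$beta)
  res <- list(out = out, mu = mu, v = v)
  if (cache) {
    res$a <- a
    res$mask <- mask
    res$hd <- hd
    res$xhat <- xhat
    res$X <- X
  }
  res
}

mlpForward <- function(params, X, dropout, training, running, cache = FALSE) {
  nH <- length(params) - 1
  caches <- vector("list", nH)
  cur <- X
  stats <- vector("list", nH)
  for (l in seq_len(nH)) {
    blk <- mlpBlockForward(cur, params[[l]], dropout, training, running[[l]], cache)
    caches[[l]] <- blk
    stats[[l]] <- list(mean = blk$mu, var = blk$v)
    cur <- blk$out
  }
  logits <- addCols(cur %*% params[[nH + 1]]$W, params[[nH + 1]]$b)
  list(logits = logits, caches = caches, stats = stats, hTop = cur)
}

# backward through one hidden block given d(out); returns gradients and dX
mlpBlockBackward <- function(dout, layer, blk, dropout, training) {
  m <- nrow(dout)
  dgamma <- colSums(dout * blk$xhat)
  dbeta <- colSums(dout)
  dxhat <- mulCols(dout, layer$gamma)
  if (training) {
    centered <- subCols(blk$hd, blk$mu)
    istd <- 1 / sqrt(blk$v + BN_EPS)
    dvar <- colSums(dxhat * centered) * (-0.5) * istd^3
    dmu <- colSums(mulCols(dxhat, -istd)) + dvar * colMeans(-2 * centered)
    dhd <- mulCols(dxhat, istd) +
      mulCols(centered, 2 * dvar / m) +
      rep(dmu / m, each = m)
  } else {
    dhd <- mulCols(dxhat, 1 / sqrt(blk$v + BN_EPS))
  }
  dh <- if (!is.null(blk$mask)) dhd * blk$mask / (1 - dropout) else dhd
  da <- dh * (blk$a > 0)
  list(
    dW = crossprod(blk$X, da),
    db = colSums(da),
    dgamma = dgamma, dbeta = dbeta,
    dX = da %*% t(layer$W)
  )
}

fitMLPModel <- function(X, y, p, seed) {
  classes <- levels(y)
  C <- length(classes)
  n <- nrow(X)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  hidden <- p$hidden
  withSeed(seed, {
    params <- mlpInit(ncol(X), hidden, C)
    running <- lapply(hidden, function(h) list(mean = rep(0, h), var = rep(1, h)))
    adam <- list(m = rapply(params, function(x) x * 0, how = "replace"),
                 v = rapply(params, function(x) x * 0, how = "replace"))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    best <- Inf; wait <- 0; t <- 0
    for (epoch in seq_len(p$epochs)) {
      fw <- mlpForward(params, X, p$dropout, TRUE, running, cache = TRUE)
      P <- softmaxRows(fw$logits)
      loss <- -mean(log(pmax(rowSums(P * Y), 1e-12)))
      # running statistics for inference (momentum 0.9)
      for (l in seq_along(running)) {
        running[[l]]$mean <- 0.9 * running[[l]]$mean + 0.1 * fw$stats[[l]]$mean
        running[[l]]$var <- 0.9 * running[[l]]$var + 0.1 * fw$stats[[l]]$var
      }
      # backward
      nH <- length(hidden)
      grads <- vector("list", nH + 1)
      dz <- (P - Y) / n
      grads[[nH + 1]] <- list(W = crossprod(fw$hTop, dz), b = colSums(dz))
      dcur <- dz %*% t(params[[nH + 1]]$W)
      for (l in rev(seq_len(nH))) {
        bb <- mlpBlockBackward(dcur, params[[l]], fw$caches[[l]], p$dropout, TRUE)
        grads[[l]] <- list(W = bb$dW, b = bb$db, gamma = bb$dgamma, beta = bb$dbeta)
        dcur <- bb$dX
      }
      # Adam update
      t <- t + 1
      for (l in seq_along(params)) {
        for (nm in names(grads[[l]])) {
          g <- grads[[l]][[nm]]
          adam$m[[l]][[nm]] <- b1 * adam$m[[l]][[nm]] + (1 - b1) * g
          adam$v[[l]][[nm]] <- b2 * adam$v[[l]][[nm]] + (1 - b2) * g^2
          mhat <- adam$m[[l]][[nm]] / (1 - b1^t)
          vhat <- adam$v[[l]][[nm]] / (1 - b2^t)
          params[[l]][[nm]] <- params[[l]][[nm]] -
            p$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      if (loss < best - p$tol) {
        best <- loss
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= p$patience) break
      }
    }
    list(
      params = params, running = running, classes = classes,
      dropout = p$dropout, hidden = hidden
    )
  })
}

mlpPredictProba <- function(st, X) {
  fw <- mlpForward(st$params, X, st$dropout, FALSE, st$running)
  P <- softmaxRows(fw$logits)
  colnames(P) <- st$classes
  P
}

# logits in inference mode (smooth deterministic function of the input)
mlpLogits <- function(st, X) {
  mlpForward(st$params, X, st$dropout, FALSE, st$running)$logits
}

# gradient of sum_i score[i, target_i] w.r.t. the inputs, inference mode;
# one batched backward pass serves every row at once. score = "logit"
# differentiates the raw class logit, score = "prob" the softmax
# probability (the output a classifier is actually read by).
mlpInputGrad <- function(st, X, targetIdx, score = c("logit", "prob")) {
  score <- match.arg(score)
  fw <- mlpForward(st$params, X, st$dropout, FALSE, st$running, cache = TRUE)
  nH <- length(st$hidden)
  C <- length(st$classes)
  n <- nrow(X)
  dz <- matrix(0, n, C)
  if (score == "logit") {
    dz[cbind(seq_len(n), targetIdx)] <- 1
  } else {
    P <- softmaxRows(fw$logits)
    pt <- P[cbind(seq_len(n), targetIdx)]
    dz <- -P * pt # softmax jacobian row for the target class
    dz[cbind(seq_len(n), targetIdx)] <- pt * (1 - pt)
  }
  dcur <- dz %*% t(st$params[[nH + 1]]$W)
  for (l in rev(seq_len(nH))) {
    bb <- mlpBlockBackward(dcur, st$params[[l]], fw$caches[[l]], st$dropout, FALSE)
    dcur <- bb$dX
  }
  dcur
}
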