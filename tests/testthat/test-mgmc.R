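test_that("meta graphs follow the similarity rules", {
  meta <- data.frame(
    age = c(30, 35, 37),
    gender = c("F", "F", "M"),
    eq5d = c(0.8, 0.86, 0.9),
    dhi = c(40, 52, 60)
  )
  g <- buildMetaGraphs(meta)
  ageA <- g@graphs[[which(g@rules$meta == "age")]]
  expect_equal(ageA[1, 2], 1) # |30 - 35| <= 6
  expect_equal(ageA[1, 3], 0) # 7 > 6
  expect_equal(ageA[2, 3], 1)
  genderA <- g@graphs[[which(g@rules$meta == "gender")]]
  expect_equal(genderA, matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3))
  eqA <- g@graphs[[which(g@rules$meta == "eq5d")]]
  expect_equal(eqA[1, 2], 1) # 0.06 <= 0.06
  expect_equal(eqA[1, 3], 0)
  # missing values produce no edges
  meta$age[2] <- NA
  g2 <- buildMetaGraphs(meta)
  expect_equal(sum(g2@graphs[[which(g2@rules$meta == "age")]][2, ]), 0)

  expect_error(buildMetaGraphs(meta[, 1:2, drop = FALSE]), "absent column")
})

test_that("scaled Laplacian follows the spectral conventions", {
  # empty graph: isolated-node convention forces L~ = -I
  expect_equal(scaledLaplacian(matrix(0, 3, 3)), -diag(3))
  # two-node single edge: L_sym = [[1,-1],[-1,1]], lambda_max = 2
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(scaledLaplacian(A), matrix(c(0, -1, -1, 0), 2))
  # eigenvalues within [-1, 1] on random graphs
  for (s in 1:5) {
    A <- withr::with_seed(s, {
      M <- matrix(rbinom(900, 1, 0.2), 30)
      M <- 1 * ((M + t(M)) > 0)
      diag(M) <- 0
      M
    })
    ev <- eigen(scaledLaplacian(A), symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-9 & ev <= 1 + 1e-9))
  }
})

test_that("Chebyshev filtering satisfies the recurrence and closed forms", {
  Lt <- matrix(c(0, -1, -1, 0), 2)
  X <- matrix(c(1, 0), 2, 1)
  expect_equal(chebyshevFilter(Lt, X, 1), X) # T_0 = I
  Z <- chebyshevFilter(Lt, X, 2)
  expect_equal(Z, cbind(X, matrix(c(0, -1), 2, 1)))
  # T_3 by recurrence equals the closed form 4 L^3 - 3 L
  A <- withr::with_seed(4, {
    M <- matrix(rbinom(400, 1, 0.3), 20)
    M <- 1 * ((M + t(M)) > 0)
    diag(M) <- 0
    M
  })
  Lt <- scaledLaplacian(A)
  Xr <- withr::with_seed(5, matrix(rnorm(20 * 3), 20, 3))
  Z4 <- chebyshevFilter(Lt, Xr, 4)
  T3X <- Z4[, 10:12]
  closed <- (4 * Lt %*% Lt %*% Lt - 3 * Lt) %*% Xr
  expect_equal(T3X, closed, tolerance = 1e-10)

  expect_error(chebyshevFilter(Lt, Xr[1:5, , drop = FALSE], 3), "dimension")
})

test_that("the summed precomputed basis equals per-graph filtering", {
  meta <- withr::with_seed(11, data.frame(
    age = rnorm(25, 50, 15), gender = sample(c("F", "M"), 25, TRUE),
    eq5d = runif(25), dhi = runif(25, 0, 100)
  ))
  graphs <- buildMetaGraphs(meta)
  basis <- mgmcBasis(graphs, chebOrder = 4)
  M <- withr::with_seed(12, matrix(rnorm(25 * 3), 25, 3))
  Z <- clinbench:::mgmcZ(M, basis$Astack, basis$G)
  ref <- Reduce(`+`, lapply(graphs@graphs, function(A) {
    chebyshevFilter(scaledLaplacian(A), M, 4)
  }))
  expect_equal(Z, ref, tolerance = 1e-10)
})

mgmcToy <- function(n = 60, d = 6, seed = 1, missFrac = 0.2, effect = 3) {
  withr::with_seed(seed, {
    y <- rep(c("a", "b"), length.out = n)
    X <- matrix(rnorm(n * d), n, d)
    X[y == "b", 1:2] <- X[y == "b", 1:2] + effect
    meta <- data.frame(
      age = rnorm(n, 50, 10) + ifelse(y == "b", 8, 0),
      gender = sample(c("F", "M"), n, TRUE),
      eq5d = runif(n), dhi = runif(n, 0, 100)
    )
    Xm <- X
    Xm[matrix(runif(n * d) < missFrac, n, d)] <- NA
    # training rows cover both classes
    trainMask <- rep(FALSE, n)
    trainMask[sample(n, n / 2)] <- TRUE
    if (length(unique(y[trainMask])) < 2) trainMask[1:2] <- TRUE
    list(X = X, Xm = Xm, y = y, graphs = buildMetaGraphs(meta),
      trainMask = trainMask)
  })
}

test_that("observed entries are reproduced after convergence", {
  # class-uninformative features: reconstruction is not traded against the
  # classification term (informative columns may be deliberately distorted
  # toward a more discriminative representation)
  toy <- mgmcToy(seed = 31, missFrac = 0.15, effect = 0)
  trainMask <- toy$trainMask
  # tight plateau tolerance so the reconstruction is actually converged
  res <- mgmcTrainPredict(toy$Xm, ifelse(trainMask, toy$y, NA), toy$graphs,
    trainMask, mgmcConfig(seed = 2, tol = 1e-7, patience = 50L, epochs = 2000L))
  obs <- !is.na(toy$Xm)
  rmse <- sqrt(mean((res$Mx[obs] - toy$Xm[obs])^2))
  expect_lt(rmse, 0.05)
  # the completed output keeps observed cells verbatim
  expect_equal(res$Xhat[obs], toy$Xm[obs])
  expect_equal(rowSums(res$P), rep(1, 60), tolerance = 1e-9)
})

test_that("test labels never influence the completion (transductive hygiene)", {
  toy <- mgmcToy(seed = 32)
  trainMask <- toy$trainMask
  yA <- ifelse(trainMask, toy$y, NA)
  yB <- toy$y
  yB[!trainMask] <- rev(toy$y[!trainMask]) # flipped/garbled test labels
  cfg <- mgmcConfig(seed = 5, epochs = 120)
  resA <- mgmcTrainPredict(toy$Xm, yA, toy$graphs, trainMask, cfg)
  resB <- mgmcTrainPredict(toy$Xm, yB, toy$graphs, trainMask, cfg)
  expect_identical(resA$P, resB$P)
  expect_identical(resA$Xhat, resB$Xhat)
})

test_that("training is deterministic under a fixed seed", {
  toy <- mgmcToy(seed = 33)
  trainMask <- toy$trainMask
  cfg <- mgmcConfig(seed = 9, epochs = 80)
  r1 <- mgmcTrainPredict(toy$Xm, ifelse(trainMask, toy$y, NA), toy$graphs, trainMask, cfg)
  r2 <- mgmcTrainPredict(toy$Xm, ifelse(trainMask, toy$y, NA), toy$graphs, trainMask, cfg)
  expect_identical(r1$P, r2$P)
  expect_identical(r1$loss, r2$loss)
})

test_that("strong smoothness drives predictions constant within communities", {
  n <- 40
  A <- matrix(0, n, n)
  A[1:20, 1:20] <- 1
  A[21:40, 21:40] <- 1
  diag(A) <- 0
  graphs <- new("MetaGraphSet", graphs = list(A),
    rules = data.frame(meta = "block", type = "equal", threshold = NA))
  X <- withr::with_seed(3, matrix(rnorm(n * 4), n, 4))
  y <- rep(c("a", "b"), each = 20)
  trainMask <- rep(c(TRUE, TRUE, FALSE, FALSE), 10)
  res <- mgmcTrainPredict(X, ifelse(trainMask, y, NA), graphs, trainMask,
    mgmcConfig(seed = 4, gamma = 25, epochs = 300))
  spread <- max(
    sd(res$P[1:20, 1]),
    sd(res$P[21:40, 1])
  )
  expect_lt(spread, 0.05)
})

test_that("degenerate inputs error or warn as declared", {
  toy <- mgmcToy(seed = 34)
  trainMask <- toy$trainMask
  allNA <- toy$Xm
  allNA[] <- NA
  expect_error(
    mgmcTrainPredict(allNA, toy$y, toy$graphs, trainMask, mgmcConfig()),
    "no observed entries"
  )
  expect_error(
    mgmcTrainPredict(toy$Xm, rep("a", 60), toy$graphs, trainMask, mgmcConfig()),
    "2 classes"
  )
  empty <- new("MetaGraphSet",
    graphs = list(matrix(0, 60, 60)),
    rules = data.frame(meta = "none", type = "equal", threshold = NA)
  )
  expect_warning(
    mgmcTrainPredict(toy$Xm, ifelse(trainMask, toy$y, NA), empty, trainMask,
      mgmcConfig(seed = 2, epochs = 30)),
    "edgeless"
  )
})
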