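test_that("the registry carries the stated parametrizations", {
  reg <- defaultRegistry()
  expect_length(reg, 11)
  expect_equal(modelDefaults(reg$SVC)$cost, 0.25)
  expect_equal(modelDefaults(reg$SVC)$kernel, "linear")
  expect_equal(modelDefaults(reg$KNN)$k, 10L)
  expect_equal(modelDefaults(reg$DT)$max_depth, 5L)
  expect_equal(modelDefaults(reg$DT)$criterion, "gini")
  expect_equal(modelDefaults(reg$RF)$n_trees, 10L)
  expect_equal(modelDefaults(reg$RF)$max_depth, 5L)
  expect_equal(modelDefaults(reg$AB)$n_estimators, 50L)
  expect_equal(modelDefaults(reg$AB)$base, "stump")
  expect_equal(modelDefaults(reg$MLP)$hidden, c(64L, 32L))
  expect_equal(modelDefaults(reg$MLP)$dropout, 0.3)
  expect_true(modelDefaults(reg$MLP)$batch_norm)
  expect_equal(modelDefaults(reg$MGMC)$timesteps, 5L)
  expect_equal(modelDefaults(reg$MGMC)$cheb_order, 5L)
  expect_true(modelDefaults(reg$MGMC)$hidden %in% c(16L, 32L, 64L))
  # LDA and GNB are fixed parametrizations with no search space
  expect_length(reg$LDA@searchSpace, 0)
  expect_length(reg$GNB@searchSpace, 0)
  expect_true(reg$MGMC@transductive)
  expect_false(any(vapply(reg[-11], function(s) s@transductive, logical(1))))
})

nonTransductive <- function() {
  reg <- defaultRegistry()
  reg[!vapply(reg, function(s) s@transductive, logical(1))]
}

test_that("every classical model separates two clouds 4 s.d. apart", {
  sep <- separableXY(n = 400, d = 10, effect = 4, seed = 21)
  trainIdx <- seq_len(300)
  for (spec in nonTransductive()) {
    m <- fitModel(spec, sep$X[trainIdx, ], sep$y[trainIdx], seed = 2)
    P <- predictProba(m, sep$X[-trainIdx, ])
    acc <- mean(m@classes[max.col(P)] == sep$y[-trainIdx])
    expect_gte(acc, 0.9)
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
    expect_true(all(P >= -1e-12))
  }
})

test_that("probability rows are stochastic on random inputs", {
  sep <- separableXY(n = 80, d = 5, effect = 1, seed = 3)
  Xnew <- matrix(rnorm(40 * 5), 40, 5)
  for (spec in nonTransductive()) {
    m <- fitModel(spec, sep$X, sep$y, seed = 4)
    P <- predictProba(m, Xnew)
    expect_equal(unname(rowSums(P)), rep(1, 40), tolerance = 1e-9)
  }
})

test_that("GNB returns (0.5, 0.5) at the midpoint of a symmetric toy", {
  X <- matrix(c(-2, -2.5, -1.5, 2, 2.5, 1.5), ncol = 1)
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  m <- fitModel(defaultRegistry("GNB")$GNB, X, y)
  P <- predictProba(m, matrix(0, 1, 1))
  expect_equal(as.numeric(P), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("decision trees respect the depth cap", {
  # alternating structure needs depth > 5 for purity
  set.seed(9)
  X <- matrix(runif(400 * 3), 400, 3)
  y <- factor(ifelse(rowSums(floor(X * 8)) %% 2 == 0, "a", "b"))
  m <- fitModel(defaultRegistry("DT")$DT, X, y)
  nodes <- as.numeric(rownames(m@state$fit$frame))
  expect_lte(max(floor(log2(nodes))), 5)
})

test_that("KNN with k = 1 returns the training point's own label", {
  sep <- separableXY(n = 30, d = 4, effect = 0.5, seed = 6)
  spec <- defaultRegistry("KNN")$KNN
  m <- fitModel(spec, sep$X, sep$y, params = list(k = 1L))
  P <- predictProba(m, sep$X)
  expect_equal(m@classes[max.col(P)], as.character(sep$y))
  expect_true(all(P %in% c(0, 1)))
})

test_that("unanimous forest votes give probability one", {
  X <- matrix(c(rnorm(50, -3, 0.1), rnorm(50, 3, 0.1)), ncol = 1)
  y <- factor(rep(c("a", "b"), each = 50))
  m <- fitModel(defaultRegistry("RF")$RF, X, y, seed = 7)
  P <- predictProba(m, matrix(c(-3, 3), 2, 1))
  expect_equal(as.numeric(P[1, "a"]), 1)
  expect_equal(as.numeric(P[2, "b"]), 1)
})

test_that("deterministic models are bit-reproducible, stochastic ones under a seed", {
  sep <- separableXY(n = 100, d = 6, effect = 2, seed = 10)
  Xnew <- matrix(rnorm(20 * 6), 20, 6)
  for (nm in c("LDA", "LR", "SVC", "GNB", "KNN", "DT", "GP", "RF", "AB", "MLP")) {
    spec <- defaultRegistry(nm)[[nm]]
    p1 <- predictProba(fitModel(spec, sep$X, sep$y, seed = 5), Xnew)
    p2 <- predictProba(fitModel(spec, sep$X, sep$y, seed = 5), Xnew)
    expect_identical(p1, p2)
  }
})

test_that("degenerate training inputs raise errors", {
  X <- matrix(rnorm(20), 10, 2)
  spec <- defaultRegistry("LR")$LR
  expect_error(fitModel(spec, X, factor(rep("a", 10))), "two classes")
  expect_error(
    fitModel(spec, X[, integer(0), drop = FALSE], factor(rep(c("a", "b"), 5))),
    "at least one column"
  )
  m <- suppressWarnings(fitModel(spec, X, factor(rep(c("a", "b"), 5))))
  expect_error(predictProba(m, matrix(0, 2, 5)), "columns")
})
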