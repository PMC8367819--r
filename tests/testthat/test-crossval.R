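test_that("stratified folds are disjoint, exhaustive and balanced", {
  labels <- rep(c("BVF", "FD"), c(66, 346))
  plan <- stratifiedFolds(labels, 10, seed = 3)
  expect_equal(sort(unique(plan@assignment)), 1:10)
  expect_length(plan@assignment, 412)
  for (f in 1:10) {
    idx <- plan@assignment == f
    expect_true(sum(labels[idx] == "BVF") %in% c(6L, 7L))
    expect_true(sum(labels[idx] == "FD") %in% c(34L, 35L))
  }
  # per fold and class: |count - class_total/k| <= 1
  for (cl in c("BVF", "FD")) {
    counts <- tabulate(plan@assignment[labels == cl], 10)
    expect_true(all(abs(counts - sum(labels == cl) / 10) <= 1))
  }
})

test_that("fold assignment is deterministic and supports leave-one-out", {
  labels <- rep(c("a", "b"), 25)
  p1 <- stratifiedFolds(labels, 5, seed = 11)
  p2 <- stratifiedFolds(labels, 5, seed = 11)
  expect_identical(p1@assignment, p2@assignment)
  expect_false(identical(p1@assignment, stratifiedFolds(labels, 5, seed = 12)@assignment))

  loo <- suppressWarnings(stratifiedFolds(labels, 50, seed = 1)) # classes < k
  expect_equal(sort(tabulate(loo@assignment, 50)), rep(1L, 50))
})

test_that("small classes degrade to a warning, k > N is fatal", {
  labels <- c(rep("a", 30), rep("b", 3))
  expect_warning(plan <- stratifiedFolds(labels, 10, seed = 2), "class 'b'")
  expect_equal(sort(unique(plan@assignment)), 1:10)
  expect_error(stratifiedFolds(c("a", "b"), 5), "exceed")
})

test_that("random search honors empty spaces, single draws and decoys", {
  sep <- separableXY(n = 80, d = 4, effect = 2, seed = 15)
  y <- sep$y

  # empty space: defaults returned, no inner folds run
  lda <- defaultRegistry("LDA")$LDA
  expect_identical(randomSearch(lda, sep$X, y, searchConfig(nIter = 5)), list())

  # a single sampled candidate is returned as-is
  knn <- defaultRegistry("KNN")$KNN
  s1 <- randomSearch(knn, sep$X, y, searchConfig(nIter = 1), seed = 4)
  expect_true(s1$k %in% c(3L, 5L, 10L, 15L, 25L))

  # the data-generating setting beats a decoy: k = 79 on 80 points is the
  # majority vote, k = 5 separates the clouds
  decoy <- new("ModelSpec",
    name = "KNN", family = "nonlinear", transductive = FALSE,
    fixedParams = list(metric = "euclidean"),
    defaultParams = list(k = 10L), searchSpace = list(k = c(5L, 79L))
  )
  best <- randomSearch(decoy, sep$X, y, searchConfig(nIter = 10), seed = 4)
  expect_equal(best$k, 5L)
})

test_that("a small benchmark produces k estimates per model and one prediction per subject", {
  gen <- quickCohort(classSizes = c(a = 24, b = 36), effect = 3, seed = 44)
  reg <- defaultRegistry(c("LDA", "DT"))
  res <- runBenchmark(gen$table, reg, k = 3,
    search = searchConfig(nIter = 2, innerK = 2), seed = 5)
  mets <- benchmarkMetrics(res)
  expect_equal(nrow(mets[mets$metric == "accuracy", ]), 2 * 3)
  preds <- pooledPredictions(res)
  for (nm in c("LDA", "DT")) {
    sub <- preds[preds$classifier == nm, ]
    expect_setequal(sub$id, subjectIds(gen$table))
    expect_equal(nrow(sub), 60)
  }
  # separable data: strong pooled accuracy
  pm <- pooledMetrics(res)
  expect_true(all(pm$accuracy > 0.85))
  # importances align with the reference encoded columns
  im <- importanceMatrix(res)
  expect_equal(colnames(im$I), res@featureNames)
  expect_equal(nrow(im$I), 2)

  # identical seed: bit-identical metric table
  res2 <- runBenchmark(gen$table, reg, k = 3,
    search = searchConfig(nIter = 2, innerK = 2), seed = 5)
  expect_identical(benchmarkMetrics(res2), mets)
})

test_that("a failing model is recorded and the benchmark continues", {
  gen <- quickCohort(seed = 46)
  boom <- new("ModelSpec",
    name = "LR", family = "linear", transductive = FALSE,
    fixedParams = list(), defaultParams = list(C = -1), searchSpace = list()
  )
  reg <- list(BOOM = boom, LDA = defaultRegistry("LDA")$LDA)
  res <- runBenchmark(gen$table, reg, k = 2,
    search = searchConfig(nIter = 1, innerK = 2), seed = 1)
  fails <- benchmarkFailures(res)
  expect_true(all(fails$classifier == "BOOM"))
  expect_equal(nrow(fails), 2)
  expect_setequal(unique(benchmarkMetrics(res)$classifier), "LDA")
})

test_that("child seed streams are independent of registry composition", {
  gen <- quickCohort(classSizes = c(a = 20, b = 30), seed = 47)
  resSolo <- runBenchmark(gen$table, defaultRegistry("RF"), k = 2,
    search = searchConfig(nIter = 1, innerK = 2), seed = 9)
  resPair <- runBenchmark(gen$table, defaultRegistry(c("LDA", "RF")), k = 2,
    search = searchConfig(nIter = 1, innerK = 2), seed = 9)
  mSolo <- benchmarkMetrics(resSolo)
  mPair <- benchmarkMetrics(resPair)
  expect_equal(
    mSolo[mSolo$classifier == "RF", ],
    mPair[mPair$classifier == "RF", ],
    ignore_attr = TRUE
  )
})

test_that("importance aggregation can exclude the permutation-fallback models", {
  gen <- quickCohort(classSizes = c(a = 20, b = 30), seed = 48)
  res <- runBenchmark(gen$table, defaultRegistry(c("LDA", "KNN")), k = 2,
    search = searchConfig(nIter = 1, innerK = 2), seed = 3)
  imAll <- importanceMatrix(res)
  imSub <- importanceMatrix(res, exclude = "KNN")
  expect_setequal(rownames(imAll$I), c("LDA", "KNN"))
  expect_setequal(rownames(imSub$I), "LDA")
})

test_that("the transductive model can consume the imputed matrix instead", {
  gen <- quickCohort(classSizes = c(a = 30, b = 30), missingRate = 0.15,
    seed = 49, dInf = 2, dNoise = 1)
  res <- runBenchmark(gen$table, defaultRegistry("MGMC"), k = 2,
    search = searchConfig(nIter = 1, innerK = 2), seed = 4,
    transductiveInput = "imputed")
  expect_equal(nrow(benchmarkFailures(res)), 0)
  expect_equal(res@config$transductiveInput, "imputed")
  pm <- pooledMetrics(res)
  expect_gt(pm$accuracy, 0.7)
})
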