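test_that("confusion matrices count true/predicted pairs", {
  cm <- confusionMatrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"), c("A", "B"))
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 2L), 2))
  expect_equal(rowSums(cm), c(A = 2, B = 2))

  perfect <- confusionMatrix(c("A", "B", "C"), c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(unname(perfect), diag(3) * 1L)
  expect_error(confusionMatrix("A", "Z", c("A", "B")), "unknown label")
})

test_that("metrics reproduce the count-based formulas", {
  # binary task: positive (minority) class with TP=3, FN=1, FP=1, TN=5
  cm <- matrix(c(3L, 1L, 1L, 5L), 2, byrow = TRUE,
    dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- classificationMetrics(cm)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$positive, "pos") # 4 true pos < 6 true neg
  expect_equal(unname(m$precision["pos"]), 0.75)
  expect_equal(unname(m$recall["pos"]), 0.75)
  expect_equal(m$f1, 0.75)

  # all-correct predictions
  y <- c("a", "a", "b")
  probs <- rbind(c(1, 0), c(0.9, 0.1), c(0.2, 0.8))
  cm2 <- confusionMatrix(y, y, c("a", "b"))
  m2 <- classificationMetrics(cm2, probs, y)
  expect_equal(m2$accuracy, 1)
  expect_equal(m2$f1, 1)
  expect_equal(m2$roc_auc, 1)

  expect_error(
    classificationMetrics(cm2, probs * 2, y),
    "sum to 1"
  )
})

test_that("metrics agree with exhaustive pair counting on random matrices", {
  withr::with_seed(77, {
    for (rep in 1:100) {
      C <- sample(2:5, 1)
      classes <- paste0("c", seq_len(C))
      cm <- matrix(rpois(C * C, 4), C, dimnames = list(classes, classes))
      storage.mode(cm) <- "integer"
      if (sum(cm) == 0) next
      m <- classificationMetrics(cm)
      # oracle: expand to individual (true, pred) pairs and count
      yt <- rep(rep(classes, C), times = as.vector(t(cm)))
      yp <- rep(rep(classes, each = C), times = as.vector(t(cm)))
      expect_equal(m$accuracy, mean(yt == yp), tolerance = 1e-12)
      f1o <- vapply(classes, function(cl) {
        tp <- sum(yt == cl & yp == cl)
        prec <- if (sum(yp == cl) > 0) tp / sum(yp == cl) else 0
        rec <- if (sum(yt == cl) > 0) tp / sum(yt == cl) else 0
        if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      }, numeric(1))
      expect_equal(unname(m$f1_macro), mean(f1o), tolerance = 1e-12)
    }
  })
})

test_that("rank-statistic AUC matches pROC including ties", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    for (rep in 1:20) {
      y <- rbinom(60, 1, 0.4) == 1
      if (!any(y) || all(y)) next
      s <- round(rnorm(60), 1) # rounding forces ties
      ours <- clinbench:::aucRank(s, y)
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = y, predictor = s, quiet = TRUE, direction = "<"
      )))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("a random scorer has chance-level AUC on balanced labels", {
  withr::with_seed(99, {
    y <- rep(c(TRUE, FALSE), 1000)
    s <- runif(2000)
    expect_gt(clinbench:::aucRank(s, y), 0.45)
    expect_lt(clinbench:::aucRank(s, y), 0.55)
  })
})

test_that("the 2D embedding is seeded, separates planted clusters, and falls back", {
  sep <- separableXY(n = 120, d = 8, effect = 6, seed = 13)
  co1 <- embed2d(sep$X, seed = 7)
  co2 <- embed2d(sep$X, seed = 7)
  expect_identical(co1, co2)
  centA <- colMeans(co1[sep$y == "a", ])
  centB <- colMeans(co1[sep$y == "b", ])
  spread <- mean(c(
    sqrt(rowSums(sweep(co1[sep$y == "a", ], 2, centA)^2)),
    sqrt(rowSums(sweep(co1[sep$y == "b", ], 2, centB)^2))
  ))
  expect_gt(sqrt(sum((centA - centB)^2)), spread)

  small <- matrix(rnorm(16), 8, 2)
  expect_warning(coSmall <- embed2d(small, seed = 1), "principal axes")
  expect_equal(dim(coSmall), c(8L, 2L))
})

test_that("hypothesis tests are routed by type, group count and normality", {
  withr::with_seed(41, {
    gauss2 <- featureHypothesisTest(
      c(rnorm(200), rnorm(200, 0.5)), rep(c("a", "b"), each = 200), "continuous"
    )
    expect_equal(gauss2$test, "t")

    expo2 <- featureHypothesisTest(
      c(rexp(200), rexp(200, 0.7)), rep(c("a", "b"), each = 200), "continuous"
    )
    expect_equal(expo2$test, "mann-whitney")

    gauss3 <- featureHypothesisTest(
      rnorm(300), rep(c("a", "b", "c"), each = 100), "continuous"
    )
    expect_equal(gauss3$test, "anova")

    expo3 <- featureHypothesisTest(
      rexp(300), rep(c("a", "b", "c"), each = 100), "continuous"
    )
    expect_equal(expo3$test, "kruskal-wallis")
  })
})

test_that("chi-squared is uncorrected and matches the closed form", {
  values <- c(rep(c("x", "y"), c(10, 20)), rep(c("x", "y"), c(20, 10)))
  labels <- rep(c("a", "b"), each = 30)
  res <- featureHypothesisTest(values, labels, "categorical")
  expect_equal(res$test, "chi-squared")
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9) # sum (O-E)^2/E, E = 15
  expect_true(res$significant)

  # closed-form oracle on random tables
  withr::with_seed(8, {
    for (rep in 1:20) {
      tab <- matrix(rpois(4, 20) + 5, 2)
      vals <- c(rep(c("x", "y"), tab[1, ]), rep(c("x", "y"), tab[2, ]))
      labs <- rep(c("a", "b"), rowSums(tab))
      res <- featureHypothesisTest(vals, labs, "categorical")
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
    }
  })
})

test_that("degenerate groups are skipped with a reason", {
  res <- featureHypothesisTest(c(1, 2, NA), c("a", "a", "b"), "continuous")
  expect_equal(res$test, "skipped")
  expect_true(is.na(res$p))
  expect_match(res$reason, "3 non-missing")
})
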