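test_that("winsorize clips to linear-interpolation percentile bounds", {
  # degenerate distribution: bounds collapse, nothing changes
  w <- winsorize(c(5, 5, 5, 5))
  expect_equal(w$values, c(5, 5, 5, 5))
  expect_equal(w$bounds, c(5, 5))

  # 101 equally spaced points: oracle gives exactly (5, 95)
  x <- 0:100
  expect_equal(percentileOracle(x, 5), 5)
  w <- winsorize(x)
  expect_equal(w$bounds, c(percentileOracle(x, 5), percentileOracle(x, 95)))
  expect_true(all(w$values >= 5 & w$values <= 95))
  expect_equal(w$values[50], 49) # interior values untouched

  # 4-point percentile, missing passes through
  w <- winsorize(c(1, NA, 1000, 2, 3))
  upper <- percentileOracle(c(1, 1000, 2, 3), 95)
  expect_equal(w$values, c(percentileOracle(c(1, 1000, 2, 3), 5), NA, upper, 2, 3))
  expect_equal(w$bounds[2], upper)

  expect_error(winsorize(c(NA_real_, NA_real_)), "missing")
  expect_error(winsorize(1:10, 95, 5), "lowerPct")
})

test_that("zscore uses population variance and honors fitted statistics", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z$values, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z$stats, c(2, sqrt(2 / 3)), tolerance = 1e-12)

  # idempotence of the statistics on already standardized data
  z2 <- zscore(z$values)
  expect_equal(z2$stats, c(0, 1), tolerance = 1e-12)

  expect_equal(zscore(12, fitStats = c(10, 2))$values, 1)

  expect_warning(zc <- zscore(c(7, 7, 7)), "constant")
  expect_equal(zc$values, c(0, 0, 0))
  expect_true(zc$constant)
})

test_that("categorical encoding is one-hot for K >= 3 and 0/1 for binary", {
  spec3 <- featureSpec("color", "categorical", c("a", "b", "c"))
  enc <- encodeCategorical(spec3, c("b", "a", NA, "c"))
  expect_equal(dim(enc), c(4L, 3L))
  expect_equal(enc[1, ], c("color=a" = 0, "color=b" = 1, "color=c" = 0))
  expect_true(all(is.na(enc[3, ])))
  expect_equal(rowSums(enc)[c(1, 2, 4)], c(1, 1, 1), ignore_attr = TRUE)

  spec2 <- featureSpec("resp", "binary", c("no", "yes"))
  enc2 <- encodeCategorical(spec2, c("yes", "no"))
  expect_equal(dim(enc2), c(2L, 1L))
  expect_equal(as.numeric(enc2), c(1, 0))

  expect_error(encodeCategorical(spec3, c("a", "z")), "'z'")
})

test_that("drop rule omits exactly the features at or above the threshold", {
  n <- 100
  df <- data.frame(
    mostly_missing = c(rnorm(40), rep(NA, 60)), # 60% -> dropped
    at_threshold = c(rnorm(50), rep(NA, 50)),   # exactly 50% -> dropped
    below = c(rnorm(55), rep(NA, 45)),          # 45% -> kept
    complete = rnorm(n),
    dx = rep(c("A", "B"), 50)
  )
  schema <- rbind(
    featureSpec("mostly_missing", "continuous"),
    featureSpec("at_threshold", "continuous"),
    featureSpec("below", "continuous"),
    featureSpec("complete", "continuous"),
    featureSpec("dx", "categorical", c("A", "B"), role = "label")
  )
  tab <- cohortTable(df, schema)
  plan <- fitPreprocess(tab)
  expect_setequal(plan@dropped, c("mostly_missing", "at_threshold"))
  fm <- applyPreprocess(plan, tab)
  expect_setequal(unique(featureOrigin(fm)), c("below", "complete"))
  expect_false(anyNA(featureValues(fm)))
})

test_that("fit data is standardized exactly and imputation uses fit means", {
  gen <- quickCohort(classSizes = c(a = 40, b = 60), missingRate = 0.1, seed = 3)
  tab <- gen$table
  plan <- fitPreprocess(tab)
  # before imputation the non-missing fit values have mean 0, sd 1
  raw <- featureValues(applyPreprocess(plan, tab, impute = FALSE))
  contCols <- plan@columns$column[plan@columns$kind == "continuous"]
  for (cn in contCols) {
    v <- raw[, cn]
    v <- v[!is.na(v)]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  }
  # standardized values stay inside the standardized winsorization bounds
  for (i in seq_len(nrow(plan@continuous))) {
    st <- plan@continuous[i, ]
    v <- raw[, st$name]
    lim <- (c(st$lower, st$upper) - st$center) / st$scale
    expect_true(all(v[!is.na(v)] >= lim[1] - 1e-9 & v[!is.na(v)] <= lim[2] + 1e-9))
  }
  # imputed cells equal the per-column fit mean
  full <- featureValues(applyPreprocess(plan, tab))
  miss <- is.na(raw)
  for (j in seq_len(ncol(full))) {
    if (any(miss[, j])) {
      expect_equal(unique(full[miss[, j], j]), plan@columns$impute[j])
    }
  }
})

test_that("the standardized imputation value maps back to the raw mean", {
  df <- data.frame(x = c(1, NA, 3), dx = c("A", "B", "A"))
  schema <- rbind(
    featureSpec("x", "continuous"),
    featureSpec("dx", "categorical", c("A", "B"), role = "label")
  )
  plan <- fitPreprocess(cohortTable(df, schema), dropThreshold = 0.5)
  st <- plan@continuous[1, ]
  imp <- plan@columns$impute[plan@columns$column == "x"]
  expect_equal(imp * st$scale + st$center, 2.0) # raw-scale mean of {1, 3}
})

test_that("apply on new data reuses fit statistics without refitting", {
  gen <- quickCohort(seed = 8)
  tab <- gen$table
  idx <- seq_len(30)
  train <- clinbench:::subsetCohort(tab, idx)
  test <- clinbench:::subsetCohort(tab, setdiff(seq_len(nSubjects(tab)), idx))
  plan <- fitPreprocess(train)
  Xte <- featureValues(applyPreprocess(plan, test))
  contCols <- plan@columns$column[plan@columns$kind == "continuous"]
  # test-fold columns need not be centered: statistics came from the fit fold
  expect_gt(max(abs(colMeans(Xte[, contCols]))), 1e-6)
  # applying the same plan twice gives identical output
  expect_identical(Xte, featureValues(applyPreprocess(plan, test)))
})

test_that("fully missing feature set is fatal with a per-feature report", {
  df <- data.frame(x = c(NA_real_, NA, 1), dx = c("A", "B", "A"))
  schema <- rbind(
    featureSpec("x", "continuous"),
    featureSpec("dx", "categorical", c("A", "B"), role = "label")
  )
  expect_error(fitPreprocess(cohortTable(df, schema), dropThreshold = 0.5), "x: 67%")
})

test_that("a fitted plan serializes to JSON with all statistics", {
  gen <- quickCohort(missingRate = 0.1, seed = 12)
  plan <- fitPreprocess(gen$table)
  path <- withr::local_tempfile(fileext = ".json")
  writePreprocessPlan(plan, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$drop_threshold, plan@dropThreshold)
  expect_equal(back$percentiles, c(5, 95))
  expect_equal(back$continuous$center, plan@continuous$center)
  expect_equal(back$columns$impute, plan@columns$impute)
})
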