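# shared fixtures, all built in code

# minimal mixed-type cohort with a known layout
tinySchema <- function() {
  rbind(
    featureSpec("age", "continuous"),
    featureSpec("sex", "binary", c("F", "M")),
    featureSpec("dx", "categorical", c("A", "B"), role = "label")
  )
}

tinyTable <- function() {
  df <- data.frame(
    age = c(10, 20, 30),
    sex = c("F", "F", "M"),
    dx = c("A", "A", "B")
  )
  cohortTable(df, tinySchema())
}

# two Gaussian clouds separated by `effect` standardized units on the
# first `dInf` features
separableXY <- function(n = 200, d = 10, effect = 4, dInf = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d)
    y <- factor(rep(c("a", "b"), length.out = n))
    X[y == "b", seq_len(dInf)] <- X[y == "b", seq_len(dInf)] + effect
    list(X = X, y = y)
  })
}

# independent linear-interpolation percentile oracle (sort + interpolate)
percentileOracle <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small synthetic cohort without categoricals for pipeline tests
quickCohort <- function(classSizes = c(a = 30, b = 30), effect = 3,
                        missingRate = 0, seed = 1, dInf = 3, dNoise = 2) {
  generateCohort(synthConfig(
    classSizes = classSizes, dInformative = dInf, dNoise = dNoise,
    effect = effect, catSpecs = list(), missingRate = missingRate, seed = seed
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
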