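#' Configuration for the synthetic-cohort generator
#'
#' The generator emulates the statistical structure of a mixed-type
#' vestibular registry table: class imbalance, class-informative and
#' pure-noise continuous features, class-conditional categoricals,
#' MCAR missingness, and the four meta features (age, gender, EQ5D,
#' DHI) that drive patient-graph construction. Defaults mirror a
#' two-class chronic-disorder task with 66 vs. 346 subjects and
#' realistic meta-feature distributions (age roughly 65 +/- 17 vs.
#' 47 +/- 15 years, EQ5D 0.8 +/- 0.2 truncated to `[0, 1]`, DHI around
#' 45 +/- 20 truncated to `[0, 100]`).
#'
#' @param classSizes named integer vector of per-class subject counts.
#' @param dInformative number of class-informative continuous features.
#' @param dNoise number of class-independent continuous noise features.
#' @param effect standardized between-class mean shift of informative
#'   features (unit s.d. Gaussians; class c has mean `effect * (c-1)`).
#' @param catSpecs list of categorical feature specs, each a list with
#'   `name`, `levels` and `probs` (C x K matrix of class-conditional
#'   level probabilities). `NULL` gives one informative binary and one
#'   three-level categorical.
#' @param missingRate MCAR missingness fraction applied to every
#'   feature and meta column (never to labels), in `[0, 1)`.
#' @param meta class-conditional meta-feature model; a list with `age`
#'   (`mean`, `sd` per class), `gender` (probability of level "F" per
#'   class), `eq5d` and `dhi` (`mean`, `sd`, truncation built in).
#' @param seed integer seed; the generator is fully deterministic.
#' @return a list of class `SynthConfig`.
#' @export
synthConfig <- function(classSizes = c(grpA = 66L, grpB = 346L),
                        dInformative = 5L, dNoise = 15L, effect = 1.0,
                        catSpecs = NULL, missingRate = 0.1,
                        meta = NULL, seed = 1L) {
  if (effect < 0) stop("effect must be nonnegative")
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must lie in [0, 1)")
  if (any(classSizes < 1)) stop("class sizes must be positive")
  if (length(classSizes) < 2) stop("at least two classes required")
  C <- length(classSizes)
  if (is.null(names(classSizes))) {
    names(classSizes) <- paste0("class", seq_len(C))
  }
  if (is.null(catSpecs)) {
    binp <- seq(0.3, 0.7, length.out = C)
    catp <- t(vapply(seq_len(C), function(ci) {
      p <- c(0.5, 0.3, 0.2)
      p[1 + (ci - 1) %% 3] <- p[1 + (ci - 1) %% 3] + 0.2
      p / sum(p)
    }, numeric(3)))
    catSpecs <- list(
      list(name = "bin1", levels = c("no", "yes"), probs = cbind(1 - binp, binp)),
      list(name = "cat1", levels = c("a", "b", "c"), probs = catp)
    )
  }
  if (is.null(meta)) {
    rec <- function(x) rep_len(x, C)
    meta <- list(
      age = list(mean = rec(c(65, 47.2)), sd = rec(c(17, 14.5))),
      gender = list(pFemale = rec(c(27 / 66, 178 / 346))),
      eq5d = list(mean = rec(0.8), sd = rec(0.2)),
      dhi = list(mean = rec(c(46.2, 43.3)), sd = rec(c(22.6, 18.4)))
    )
  }
  structure(
    list(
      classSizes = classSizes, dInformative = as.integer(dInformative),
      dNoise = as.integer(dNoise), effect = effect, catSpecs = catSpecs,
      missingRate = missingRate, meta = meta, seed = as.integer(seed)
    ),
    class = "SynthConfig"
  )
}

rtrunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic cohort
#'
#' Draws a seeded [CohortTable] under a [synthConfig()] plus the ground
#' truth needed by recovery experiments (which features are
#' informative, the parameters used, the seed).
#'
#' @param cfg a [synthConfig()].
#' @return list with elements `table` ([CohortTable]) and `truth`
#'   (list: `informative`, `effect`, `classSizes`, `seed`).
#' @examples
#' gen <- generateCohort(synthConfig(classSizes = c(a = 20, b = 30), seed = 7))
#' gen$table
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  C <- length(cfg$classSizes)
  n <- sum(cfg$classSizes)
  cls <- rep(names(cfg$classSizes), cfg$classSizes)
  withSeed(cfg$seed, {
    df <- data.frame(row.names = seq_len(n))
    schema <- featureSpec("class", "categorical",
      categories = names(cfg$classSizes), role = "label"
    )
    infNames <- if (cfg$dInformative > 0) paste0("inf", seq_len(cfg$dInformative)) else character()
    for (j in seq_len(cfg$dInformative)) {
      mu <- cfg$effect * (match(cls, names(cfg$classSizes)) - 1)
      df[[infNames[j]]] <- rnorm(n, mean = mu, sd = 1)
      schema <- rbind(schema, featureSpec(infNames[j], "continuous"))
    }
    for (j in seq_len(cfg$dNoise)) {
      nm <- paste0("noise", j)
      df[[nm]] <- rnorm(n)
      schema <- rbind(schema, featureSpec(nm, "continuous"))
    }
    for (spec in cfg$catSpecs) {
      ci <- match(cls, names(cfg$classSizes))
      draw <- vapply(ci, function(c0) {
        sample(spec$levels, 1, prob = spec$probs[c0, ])
      }, character(1))
      df[[spec$name]] <- draw
      kind <- if (length(spec$levels) == 2) "binary" else "categorical"
      schema <- rbind(schema, featureSpec(spec$name, kind, spec$levels))
    }
    ci <- match(cls, names(cfg$classSizes))
    df$age <- round(rtrunc(n, cfg$meta$age$mean[ci], cfg$meta$age$sd[ci], 18, 95), 1)
    df$gender <- ifelse(rbinom(n, 1, cfg$meta$gender$pFemale[ci]) == 1, "F", "M")
    df$eq5d <- round(rtrunc(n, cfg$meta$eq5d$mean[ci], cfg$meta$eq5d$sd[ci], 0, 1), 3)
    df$dhi <- round(rtrunc(n, cfg$meta$dhi$mean[ci], cfg$meta$dhi$sd[ci], 0, 100), 1)
    schema <- rbind(
      schema,
      featureSpec("age", "continuous", role = "meta"),
      featureSpec("gender", "binary", c("F", "M"), role = "meta"),
      featureSpec("eq5d", "continuous", role = "meta"),
      featureSpec("dhi", "continuous", role = "meta")
    )
    # MCAR mask over feature and meta columns, never labels
    if (cfg$missingRate > 0) {
      for (nm in setdiff(names(df), "class")) {
        hit <- runif(n) < cfg$missingRate
        df[[nm]][hit] <- NA
      }
    }
    df$class <- cls
    table <- cohortTable(df, schema)
    list(
      table = table,
      truth = list(
        informative = infNames, effect = cfg$effect,
        classSizes = cfg$classSizes, seed = cfg$seed
      )
    )
  })
}

#' Permute class labels (leakage null)
#'
#' Randomly permutes the labels of a cohort while leaving every feature
#' untouched; class marginals are preserved. Any classifier run on the
#' permuted cohort should perform at the majority-class rate — a
#' leakage guard for the whole pipeline.
#'
#' @param table a [CohortTable].
#' @param seed integer seed.
#' @return a [CohortTable] with shuffled labels.
#' @export
permuteLabels <- function(table, seed = 1L) {
  withSeed(childSeed(seed, "permute"), {
    perm <- sample.int(nSubjects(table))
    new("CohortTable",
      values = table@values, schema = table@schema,
      labels = table@labels[perm], ids = table@ids
    )
  })
}
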