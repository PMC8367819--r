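#' Winsorize a numeric vector at percentile bounds
#'
#' Clips extreme values to the 5th and 95th percentile of the fit data
#' by default (a 90% winsorization). Percentiles use the linear
#' interpolation between order statistics convention
#' (`quantile(type = 7)`). Missing entries pass through unchanged.
#'
#' @param values numeric vector, may contain `NA`.
#' @param lowerPct,upperPct percentiles in `[0, 100]`, lower < upper.
#' @param bounds optional fitted bounds `c(lower, upper)`; when given,
#'   the percentiles of `values` are not recomputed (apply mode).
#' @return list with `values` (clipped) and `bounds`.
#' @examples
#' winsorize(c(1, NA, 1000, 2, 3))
#' @export
winsorize <- function(values, lowerPct = 5, upperPct = 95, bounds = NULL) {
  if (is.null(bounds)) {
    obs <- values[!is.na(values)]
    if (length(obs) == 0) stop("winsorize: all values are missing")
    if (!(lowerPct >= 0 && lowerPct < upperPct && upperPct <= 100)) {
      stop("winsorize: need 0 <= lowerPct < upperPct <= 100")
    }
    bounds <- unname(quantile(obs, c(lowerPct, upperPct) / 100, type = 7))
  }
  out <- pmin(pmax(values, bounds[1]), bounds[2])
  list(values = out, bounds = bounds)
}

#' Z-transform a numeric vector
#'
#' Standardizes to zero mean and unit variance using the population
#' (1/N) variance convention. With `fitStats` supplied the stored
#' statistics are applied without refitting. A zero-variance feature is
#' flagged constant and emitted as all zeros with a warning.
#'
#' @param values numeric vector, may contain `NA`.
#' @param fitStats optional `c(mean, sd)` from a previous fit.
#' @return list with `values`, `stats = c(mean, sd)` and `constant`.
#' @export
zscore <- function(values, fitStats = NULL) {
  constant <- FALSE
  if (is.null(fitStats)) {
    obs <- values[!is.na(values)]
    if (length(obs) == 0) stop("zscore: all values are missing")
    m <- mean(obs)
    s <- sqrt(mean((obs - m)^2))
    if (s == 0) {
      warning("zscore: zero-variance feature flagged constant, emitted as all-zeros")
      constant <- TRUE
      s <- 1
    }
    fitStats <- c(m, s)
  } else if (fitStats[2] <= 0) {
    constant <- TRUE
    fitStats[2] <- 1
  }
  out <- (values - fitStats[1]) / fitStats[2]
  if (constant) out[!is.na(out)] <- 0
  list(values = out, stats = fitStats, constant = constant)
}

#' One-hot / binary encoding of a categorical column
#'
#' K >= 3 categories produce K sparse 0/1 columns (one per category);
#' two categories are binarized into a single 0/1 column in which the
#' second category maps to 1. Missing rows are missing in every
#' produced column.
#'
#' @param feature one schema row ([featureSpec()]).
#' @param column character vector of category labels.
#' @return numeric matrix with named columns.
#' @export
encodeCategorical <- function(feature, column) {
  cats <- feature$categories[[1]]
  unknown <- which(!is.na(column) & !(column %in% cats))
  if (length(unknown)) {
    stop(sprintf(
      "unseen category label '%s' in feature '%s'",
      column[unknown[1]], feature$name
    ))
  }
  if (length(cats) == 2) {
    out <- matrix(as.numeric(column == cats[2]), ncol = 1)
    colnames(out) <- paste0(feature$name, "=", cats[2])
  } else {
    out <- vapply(cats, function(cc) as.numeric(column == cc), numeric(length(column)))
    out <- matrix(out, ncol = length(cats))
    out[is.na(column), ] <- NA_real_
    colnames(out) <- paste0(feature$name, "=", cats)
  }
  out
}

#' Fit the preprocessing plan on a training cohort
#'
#' Features whose fit missingness is at or above `dropThreshold` are
#' omitted from the patient representation (mean imputation is only
#' admissible while fewer than half the values are missing).
#' For retained continuous features, winsorization bounds and
#' population standardization statistics are fitted on the non-missing
#' values; every encoded column receives the mean of its non-missing
#' fit rows as imputation value (so one-hot columns of a missing
#' categorical impute to fractional category frequencies).
#'
#' @param table a [CohortTable] (training rows only; fitting on the full
#'   data is a deliberate config choice, see [runBenchmark()]).
#' @param dropThreshold missing fraction at or above which a feature is
#'   omitted; default 0.5.
#' @param percentiles winsorization percentile pair, default `c(5, 95)`.
#' @return a [PreprocessPlan].
#' @export
fitPreprocess <- function(table, dropThreshold = 0.5, percentiles = c(5, 95)) {
  feat <- schemaFeatures(table@schema)
  n <- nSubjects(table)
  frac <- vapply(feat$name, function(nm) mean(is.na(table@values[[nm]])), numeric(1))
  report <- data.frame(name = feat$name, missing_frac = unname(frac))
  dropped <- feat$name[frac >= dropThreshold]
  keep <- feat[!(feat$name %in% dropped), , drop = FALSE]
  if (nrow(keep) == 0) {
    stop(paste(
      "fatal: every feature exceeds the missingness threshold;",
      paste(sprintf("%s: %.0f%%", report$name, 100 * report$missing_frac), collapse = ", ")
    ))
  }
  cont <- data.frame(
    name = character(), lower = numeric(), upper = numeric(),
    center = numeric(), scale = numeric(), constant = logical()
  )
  cols <- data.frame(
    column = character(), source = character(), kind = character(),
    category = character(), impute = numeric()
  )
  catmaps <- list()
  for (i in seq_len(nrow(keep))) {
    fi <- keep[i, ]
    col <- table@values[[fi$name]]
    if (fi$kind == "continuous") {
      w <- winsorize(col, percentiles[1], percentiles[2])
      z <- zscore(w$values)
      cont <- rbind(cont, data.frame(
        name = fi$name, lower = w$bounds[1], upper = w$bounds[2],
        center = z$stats[1], scale = z$stats[2], constant = z$constant
      ))
      cols <- rbind(cols, data.frame(
        column = fi$name, source = fi$name, kind = "continuous",
        category = NA_character_, impute = mean(z$values, na.rm = TRUE)
      ))
    } else {
      enc <- encodeCategorical(fi, col)
      catmaps[[fi$name]] <- fi$categories[[1]]
      cats <- if (ncol(enc) == 1) fi$categories[[1]][2] else fi$categories[[1]]
      cols <- rbind(cols, data.frame(
        column = colnames(enc), source = fi$name, kind = fi$kind,
        category = cats, impute = colMeans(enc, na.rm = TRUE)
      ))
    }
  }
  rownames(cols) <- NULL
  new("PreprocessPlan",
    continuous = cont, columns = cols, catmaps = catmaps,
    dropped = dropped, dropThreshold = dropThreshold,
    percentiles = percentiles, missingReport = report
  )
}

#' Serialize a fitted preprocessing plan to JSON
#'
#' Writes every fitted statistic (clip bounds, standardization, category
#' maps, imputation values, drop list) for provenance, so the exact
#' transformation applied to a benchmark can be archived and audited.
#'
#' @param plan a [PreprocessPlan].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
writePreprocessPlan <- function(plan, path) {
  jsonlite::write_json(list(
    drop_threshold = plan@dropThreshold,
    percentiles = plan@percentiles,
    dropped = plan@dropped,
    continuous = plan@continuous,
    columns = plan@columns,
    category_maps = plan@catmaps,
    missing_report = plan@missingReport
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Apply a fitted preprocessing plan
#'
#' Per feature: winsorize then z-transform (continuous, with the fitted
#' statistics — no refit) or encode (categorical); then mean-impute
#' every remaining missing cell with the plan's per-column value.
#' Encoded 0/1 columns are never clipped or standardized.
#'
#' @param plan a [PreprocessPlan].
#' @param table a [CohortTable] with a schema compatible with the plan.
#' @param impute impute missing cells (default). `FALSE` keeps `NA`s,
#'   the input convention of the transductive completion model.
#' @return a [FeatureMatrix]; with `impute = TRUE` it contains no
#'   missing entries and excludes dropped features.
#' @export
applyPreprocess <- function(plan, table, impute = TRUE) {
  absent <- setdiff(unique(plan@columns$source), names(table@values))
  if (length(absent)) {
    stop(sprintf("column '%s' required by the plan is absent from the table", absent[1]))
  }
  n <- nSubjects(table)
  feat <- schemaFeatures(table@schema)
  blocks <- list()
  for (src in unique(plan@columns$source)) {
    kind <- plan@columns$kind[match(src, plan@columns$source)]
    col <- table@values[[src]]
    if (kind == "continuous") {
      st <- plan@continuous[plan@continuous$name == src, ]
      w <- winsorize(col, bounds = c(st$lower, st$upper))
      z <- zscore(w$values, fitStats = c(st$center, if (st$constant) 0 else st$scale))
      block <- matrix(z$values, ncol = 1)
      colnames(block) <- src
    } else {
      fi <- feat[feat$name == src, , drop = FALSE]
      block <- encodeCategorical(fi, col)
    }
    blocks[[src]] <- block
  }
  X <- do.call(cbind, blocks)
  X <- X[, plan@columns$column, drop = FALSE]
  if (impute) {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- plan@columns$impute[j]
    }
  }
  rownames(X) <- table@ids
  new("FeatureMatrix", X = X, origin = plan@columns$source)
}
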