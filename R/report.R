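utils::globalVariables(c(
  "classifier", "value", "metric", "class_", "share", "dim1", "dim2",
  "label", "true", "predicted", "count"
))

# per-class summary strings (mean (s.d.) or level counts) for the
# importance table layout
featureClassSummary <- function(table, feature) {
  feat <- schemaFeatures(table@schema)
  kind <- feat$kind[feat$name == feature]
  classes <- levels(table@labels)
  if (!length(kind)) {
    return(setNames(rep(NA_character_, length(classes)), classes))
  }
  col <- table@values[[feature]]
  out <- vapply(classes, function(cl) {
    v <- col[table@labels == cl]
    if (kind == "continuous") {
      v <- as.numeric(v)
      sprintf("%.2f (%.2f)", mean(v, na.rm = TRUE),
        if (sum(!is.na(v)) >= 2) sd(v, na.rm = TRUE) else NA_real_)
    } else {
      cats <- feat$categories[feat$name == feature][[1]]
      paste(vapply(cats, function(cc) sum(v == cc, na.rm = TRUE), integer(1)),
        collapse = "/")
    }
  }, character(1))
  setNames(out, classes)
}

#' Render the multi-panel benchmark report
#'
#' Writes a static panel image (metric boxplots over folds, a class
#' balance pie, the 2D input embedding colored by class, and confusion
#' heatmaps for a classifier subset) plus machine-readable siblings for
#' every number shown: `metrics.csv`, `pooled_metrics.csv`,
#' `confusions.json`, `embedding.csv`, `importance_table.csv` and a
#' `manifest.json` sufficient to re-run the benchmark bit-identically.
#'
#' @param result a [BenchmarkResult].
#' @param agg an [AggregatedImportance] (see [rafiAggregate()]); may be
#'   `NULL` to skip the importance table.
#' @param tests data.frame of per-feature hypothesis tests
#'   ([cohortFeatureTests()]); may be `NULL`.
#' @param outDir output directory (created if needed; must be writable).
#' @param table optional [CohortTable]; enables the embedding panel and
#'   the per-class summary columns of the importance table.
#' @param confusionSubset classifiers whose confusion matrices are drawn
#'   (default LR, MGMC, RF; silently reduced to those present).
#' @param topK rows of the importance table (default 10).
#' @param seed seed for the embedding.
#' @return invisible character vector of the files written.
#' @export
renderReport <- function(result, agg = NULL, tests = NULL, outDir,
                         table = NULL,
                         confusionSubset = c("LR", "MGMC", "RF"),
                         topK = 10L, seed = 1L) {
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", outDir))
  }
  probe <- file.path(outDir, ".write_probe")
  ok <- tryCatch({ writeLines("", probe); TRUE }, error = function(e) FALSE,
    warning = function(w) FALSE)
  if (!ok) stop(sprintf("output directory '%s' is not writable", outDir))
  unlink(probe)

  files <- character()
  wr <- function(df, name) {
    path <- file.path(outDir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  metrics <- result@metrics
  wr(metrics, "metrics.csv")
  wr(pooledMetrics(result), "pooled_metrics.csv")
  wr(result@predictions, "predictions.csv")

  # confusion matrices for every classifier, as JSON
  preds <- result@predictions
  confusions <- lapply(split(preds, preds$classifier), function(sub) {
    confusionMatrix(sub$label, sub$prediction, result@classes)
  })
  cpath <- file.path(outDir, "confusions.json")
  jsonlite::write_json(
    list(classes = result@classes, counts = confusions), cpath,
    auto_unbox = TRUE, pretty = TRUE
  )
  files <- c(files, cpath)

  emb <- NULL
  if (!is.null(table)) {
    pp <- fitPreprocess(table)
    X <- featureValues(applyPreprocess(pp, table))
    emb <- as.data.frame(embed2d(X, seed = seed))
    emb$label <- as.character(cohortLabels(table))
    emb$id <- subjectIds(table)
    wr(emb, "embedding.csv")
  }

  if (!is.null(agg)) {
    top <- topFeatures(agg, topK)
    if (!is.null(tests)) {
      top <- merge(top, tests, by = "feature", all.x = TRUE, sort = FALSE)
      top <- top[order(top$rank), ]
    }
    if (!is.null(table)) {
      for (cl in levels(cohortLabels(table))) {
        top[[paste0("summary_", cl)]] <- vapply(top$feature, function(fn) {
          featureClassSummary(table, fn)[[cl]]
        }, character(1))
      }
    }
    wr(top, "importance_table.csv")
  }

  manifest <- list(
    package = "clinbench",
    version = as.character(utils::packageVersion("clinbench")),
    config = result@config,
    classes = result@classes,
    n_subjects = length(result@foldPlan@assignment),
    failed = if (nrow(result@failures)) result@failures else list(),
    failed_models = setdiff(
      result@config$models, unique(result@metrics$classifier)
    ),
    files = basename(files)
  )
  mpath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, mpath)

  panel <- reportPanel(result, emb, confusionSubset)
  ppath <- file.path(outDir, "panel.png")
  grDevices::png(ppath, width = 1600, height = 1200, res = 130)
  print(panel)
  grDevices::dev.off()
  files <- c(files, ppath)
  invisible(files)
}

#' Rebuild the panel image from saved report files
#'
#' Re-renders `panel.png` from the machine-readable siblings
#' (`metrics.csv`, `predictions.csv`, optional `embedding.csv`) written
#' by [renderReport()], without re-running any model.
#'
#' @param dir directory holding a previous report.
#' @param confusionSubset classifiers to draw confusion matrices for.
#' @return invisible path of the regenerated image.
#' @export
rerenderPanel <- function(dir, confusionSubset = c("LR", "MGMC", "RF")) {
  mfile <- file.path(dir, "metrics.csv")
  pfile <- file.path(dir, "predictions.csv")
  if (!file.exists(mfile) || !file.exists(pfile)) {
    stop("directory does not contain metrics.csv / predictions.csv")
  }
  metrics <- utils::read.csv(mfile)
  preds <- utils::read.csv(pfile, colClasses = "character")
  preds$fold <- as.integer(preds$fold)
  classes <- sort(unique(preds$label))
  efile <- file.path(dir, "embedding.csv")
  emb <- if (file.exists(efile)) utils::read.csv(efile) else NULL
  fake <- new("BenchmarkResult",
    metrics = metrics, predictions = preds, probabilities = list(),
    hyperparameters = list(), importances = list(),
    failures = data.frame(),
    foldPlan = new("FoldPlan", k = max(preds$fold), assignment = rep(1L, 2),
      seed = 0L),
    featureNames = "x", featureOrigin = "x", classes = classes,
    config = list()
  )
  ppath <- file.path(dir, "panel.png")
  grDevices::png(ppath, width = 1600, height = 1200, res = 130)
  print(reportPanel(fake, emb, confusionSubset))
  grDevices::dev.off()
  invisible(ppath)
}

reportPanel <- function(result, emb = NULL, confusionSubset = c("LR", "MGMC", "RF")) {
  metrics <- result@metrics
  main <- metrics[metrics$metric %in% c("accuracy", "f1", "roc_auc"), ]
  pBox <- ggplot2::ggplot(main, ggplot2::aes(x = classifier, y = value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::theme_bw(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Cross-validated metrics")

  preds <- result@predictions
  one <- preds[preds$classifier == preds$classifier[1], ]
  bal <- as.data.frame(table(one$label))
  names(bal) <- c("class_", "count")
  bal$share <- bal$count / sum(bal$count)
  pPie <- ggplot2::ggplot(bal, ggplot2::aes(x = "", y = share, fill = class_)) +
    ggplot2::geom_col(width = 1, color = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::theme_void(base_size = 9) +
    ggplot2::labs(fill = NULL, title = "Class balance")

  pEmb <- if (!is.null(emb)) {
    ggplot2::ggplot(emb, ggplot2::aes(dim1, dim2, color = label)) +
      ggplot2::geom_point(size = 0.7, alpha = 0.8) +
      ggplot2::theme_bw(base_size = 9) +
      ggplot2::labs(title = "2D input embedding", color = NULL)
  } else {
    ggplot2::ggplot() + ggplot2::theme_void()
  }

  subset <- intersect(confusionSubset, unique(preds$classifier))
  cms <- lapply(subset, function(nm) {
    sub <- preds[preds$classifier == nm, ]
    cm <- confusionMatrix(sub$label, sub$prediction, result@classes)
    df <- as.data.frame(as.table(cm))
    names(df) <- c("true", "predicted", "count")
    df$classifier <- nm
    df
  })
  pCm <- if (length(cms)) {
    cmdf <- do.call(rbind, cms)
    ggplot2::ggplot(cmdf, ggplot2::aes(predicted, true, fill = count)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = count), size = 2.6) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue", guide = "none") +
      ggplot2::facet_wrap(~classifier, nrow = 1) +
      ggplot2::theme_bw(base_size = 9) +
      ggplot2::labs(title = "Confusion matrices (pooled out-of-fold)")
  } else {
    ggplot2::ggplot() + ggplot2::theme_void()
  }

  right <- patchwork::wrap_plots(pPie, pEmb, ncol = 1)
  top <- patchwork::wrap_plots(pBox, right, nrow = 1)
  patchwork::wrap_plots(top, pCm, ncol = 1, heights = c(2, 1))
}
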