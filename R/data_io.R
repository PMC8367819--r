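#' Declare one feature of a cohort schema
#'
#' A schema is a data.frame with one row per column of the patient
#' table. Binary features are stored as categorical with exactly two
#' categories and are later encoded as a single 0/1 column.
#'
#' @param name column name as it appears in the table header.
#' @param kind one of `"continuous"`, `"binary"`, `"categorical"`.
#' @param categories character vector of category levels (required for
#'   binary/categorical, must be empty for continuous).
#' @param role one of `"feature"`, `"label"`, `"meta"`, `"ignore"`.
#'   `meta` columns are ordinary features that additionally drive
#'   patient-graph construction for the transductive model.
#' @return one-row schema data.frame; rows can be `rbind`-ed.
#' @examples
#' rbind(
#'   featureSpec("age", "continuous", role = "meta"),
#'   featureSpec("sex", "binary", c("F", "M"), role = "meta"),
#'   featureSpec("dx", "categorical", c("caseA", "caseB"), role = "label")
#' )
#' @export
featureSpec <- function(name, kind = c("continuous", "binary", "categorical"),
                        categories = character(), role = "feature") {
  kind <- match.arg(kind)
  role <- match.arg(role, ROLE_LEVELS)
  if (kind == "continuous" && length(categories)) {
    stop("continuous features take no categories")
  }
  if (kind == "binary" && length(categories) != 2) {
    stop(sprintf("binary feature '%s' needs exactly 2 categories", name))
  }
  if (kind == "categorical" && length(categories) < 2 && role != "label") {
    stop(sprintf("categorical feature '%s' needs >= 2 categories", name))
  }
  data.frame(
    name = name, kind = kind, role = role,
    categories = I(list(as.character(categories))),
    stringsAsFactors = FALSE
  )
}

#' Read a feature schema from JSON or YAML
#'
#' The file holds a list of objects with fields `name`, `kind`,
#' optional `categories` and optional `role` (default `"feature"`).
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return schema data.frame as produced by [featureSpec()].
#' @export
readSchema <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("schema must be .json, .yaml or .yml")
  )
  rows <- lapply(raw, function(item) {
    featureSpec(
      name = item$name,
      kind = item$kind,
      categories = as.character(unlist(item$categories)),
      role = if (is.null(item$role)) "feature" else item$role
    )
  })
  schema <- do.call(rbind, rows)
  checkSchema(schema)
  schema
}

#' Write a schema to JSON
#'
#' @param schema schema data.frame.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
writeSchema <- function(schema, path) {
  items <- lapply(seq_len(nrow(schema)), function(i) {
    out <- list(
      name = schema$name[i], kind = schema$kind[i], role = schema$role[i]
    )
    cats <- schema$categories[[i]]
    if (length(cats)) out$categories <- as.list(cats)
    out
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

checkSchema <- function(schema) {
  if (anyDuplicated(schema$name)) stop("schema error: duplicated feature names")
  if (sum(schema$role == "label") != 1) {
    stop("schema error: exactly one column must have role = 'label'")
  }
  invisible(schema)
}

#' Assemble a CohortTable from an in-memory data.frame
#'
#' @param df data.frame holding (at least) every schema column; the
#'   label column must be present and complete.
#' @param schema schema data.frame ([featureSpec()] rows).
#' @param ids optional subject identifiers; defaults to the 0-based row
#'   index.
#' @param missing character values treated as missing in character
#'   columns (case-insensitive), in addition to `NA`.
#' @return a [CohortTable].
#' @export
cohortTable <- function(df, schema, ids = NULL, missing = c("", "na")) {
  checkSchema(schema)
  absent <- setdiff(schema$name[schema$role != "ignore"], names(df))
  if (length(absent)) {
    stop(sprintf("schema error: column(s) %s absent from table", paste(absent, collapse = ", ")))
  }
  n <- nrow(df)
  labCol <- schema$name[schema$role == "label"]
  labRaw <- markMissing(as.character(df[[labCol]]), missing)
  if (anyNA(labRaw)) {
    stop(sprintf("fatal: label column '%s' contains missing values; labels may not be imputed", labCol))
  }
  labLevels <- schema$categories[[which(schema$role == "label")]]
  if (!length(labLevels)) labLevels <- sort(unique(labRaw))
  bad <- setdiff(unique(labRaw), labLevels)
  if (length(bad)) {
    stop(sprintf("schema error: unknown class label '%s' in column '%s'", bad[1], labCol))
  }
  feat <- schemaFeatures(schema)
  values <- data.frame(row.names = seq_len(n))
  for (i in seq_len(nrow(feat))) {
    fi <- feat[i, ]
    col <- df[[fi$name]]
    if (fi$kind == "continuous") {
      if (!is.numeric(col)) {
        col <- suppressWarnings(as.numeric(markMissing(as.character(col), missing)))
      }
      values[[fi$name]] <- col
    } else {
      chr <- markMissing(as.character(col), missing)
      unknown <- which(!is.na(chr) & !(chr %in% fi$categories[[1]]))
      if (length(unknown)) {
        stop(sprintf(
          "schema error: unknown category label '%s' at row %d, column '%s'",
          chr[unknown[1]], unknown[1], fi$name
        ))
      }
      values[[fi$name]] <- chr
    }
  }
  if (is.null(ids)) ids <- as.character(seq_len(n) - 1L)
  new("CohortTable",
    values = values, schema = schema,
    labels = factor(labRaw, levels = labLevels), ids = as.character(ids)
  )
}

markMissing <- function(x, missing) {
  x[tolower(trimws(x)) %in% tolower(missing)] <- NA_character_
  x
}

#' Load a delimited patient table against a schema
#'
#' Cells that are empty, match a declared missing marker, or fail to
#' parse under the declared kind become missing. Row order is preserved.
#' The label column may not contain missing values.
#'
#' @param path CSV/TSV file with a header row (delimiter chosen by
#'   extension, comma unless `.tsv`/`.txt`).
#' @param schema schema data.frame or path to a JSON/YAML schema file.
#' @param missing missing-value markers (case-insensitive); registry
#'   exports vary, default treats `""` and `"NA"` as missing.
#' @param id optional header column holding subject identifiers.
#' @return a [CohortTable].
#' @export
loadCohort <- function(path, schema, missing = c("", "na"), id = NULL) {
  if (is.character(schema) && length(schema) == 1) schema <- readSchema(schema)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep, colClasses = "character",
    check.names = FALSE, na.strings = NULL, quote = "\"",
    comment.char = ""
  )
  ids <- if (!is.null(id)) {
    if (!id %in% names(df)) stop(sprintf("schema error: id column '%s' absent from header", id))
    df[[id]]
  } else NULL
  cohortTable(df, schema, ids = ids, missing = missing)
}

#' Write a CohortTable back to CSV
#'
#' Missing cells are written as empty strings, so a
#' load -> write -> load round trip reproduces values, missingness and
#' labels exactly.
#'
#' @param table a [CohortTable].
#' @param path output `.csv` path.
#' @param schemaPath optional path for a JSON copy of the schema.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(table, path, schemaPath = NULL) {
  df <- table@values
  labCol <- table@schema$name[table@schema$role == "label"]
  df[[labCol]] <- as.character(table@labels)
  utils::write.table(df, path,
    sep = ",", na = "", row.names = FALSE, quote = FALSE
  )
  if (!is.null(schemaPath)) writeSchema(table@schema, schemaPath)
  invisible(path)
}

#' Per-class cohort summary
#'
#' One row per class with its subject count and, per summary column,
#' the sample mean and s.d. of continuous features (missing values
#' excluded, non-missing count reported) or per-level counts of
#' binary/categorical features.
#'
#' @param table a [CohortTable].
#' @param columns features to summarize; defaults to the meta columns
#'   when any are declared, otherwise all features.
#' @return data.frame with columns `class`, `N`, then per continuous
#'   feature `<f>_mean`, `<f>_sd`, `<f>_n` and per category level
#'   `<f>_<level>` counts.
#' @export
summarizeCohort <- function(table, columns = NULL) {
  sc <- table@schema
  feat <- schemaFeatures(sc)
  if (is.null(columns)) {
    columns <- sc$name[sc$role == "meta"]
    if (!length(columns)) columns <- feat$name
  }
  bad <- setdiff(columns, feat$name)
  if (length(bad)) stop(sprintf("unknown summary column '%s'", bad[1]))
  classes <- levels(droplevels(table@labels)) # observed classes only
  out <- data.frame(class = classes, N = as.integer(table(table@labels)[classes]))
  for (nm in columns) {
    kind <- feat$kind[feat$name == nm]
    col <- table@values[[nm]]
    if (kind == "continuous") {
      out[[paste0(nm, "_mean")]] <- vapply(classes, function(cl) {
        mean(col[table@labels == cl], na.rm = TRUE)
      }, numeric(1))
      out[[paste0(nm, "_sd")]] <- vapply(classes, function(cl) {
        v <- col[table@labels == cl & !is.na(col)]
        if (length(v) >= 2) sd(v) else NA_real_
      }, numeric(1))
      out[[paste0(nm, "_n")]] <- vapply(classes, function(cl) {
        sum(!is.na(col[table@labels == cl]))
      }, integer(1))
    } else {
      cats <- feat$categories[feat$name == nm][[1]]
      for (lev in cats) {
        out[[paste(nm, lev, sep = "_")]] <- vapply(classes, function(cl) {
          sum(col[table@labels == cl] == lev, na.rm = TRUE)
        }, integer(1))
      }
    }
  }
  rownames(out) <- NULL
  out
}

# row subset preserving class levels; used by the cross-validation loop
subsetCohort <- function(table, idx) {
  new("CohortTable",
    values = table@values[idx, , drop = FALSE],
    schema = table@schema,
    labels = factor(as.character(table@labels[idx]), levels = levels(table@labels)),
    ids = table@ids[idx]
  )
}
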