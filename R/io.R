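#' Read and write score-matrix files
#'
#' The on-disk score format is long-by-model: one row per (sample, model)
#' pair with columns `sample_id`, `model_id`, then one column per class
#' holding that model's confidence for the class. The JSON layout is the
#' equivalent array of records, with class scores nested under `"scores"`.
#' Both round-trip losslessly: numbers are written with 17 significant
#' digits, enough to reproduce any double exactly.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @param samples named list of [score_matrix()] objects (names are sample
#'   ids; unnamed lists get `S1..Sn`).
#' @return `read_scores()`: a named list of `score_matrix` objects, in file
#'   order. `write_scores()`: the path, invisibly.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_data("score file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character")
    if (!nrow(df)) stop_data("score file is empty: ", path)
    need <- c("sample_id", "model_id")
    if (!all(need %in% names(df))) {
      stop_data("score CSV must have sample_id and model_id columns")
    }
    class_ids <- setdiff(names(df), need)
    if (length(class_ids) < 2L) {
      stop_data("score CSV needs at least two class columns")
    }
    vals <- as.matrix(df[class_ids])
    storage.mode(vals) <- "double"
    split_rows <- split(seq_len(nrow(df)), factor(df$sample_id,
                                                  levels = unique(df$sample_id)))
    out <- lapply(split_rows, function(idx) {
      score_matrix(vals[idx, , drop = FALSE],
                   model_ids = df$model_id[idx], class_ids = class_ids)
    })
    return(out)
  }
  if (ext == "json") {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!length(recs)) stop_data("score file is empty: ", path)
    sample_ids <- vapply(recs, `[[`, character(1L), "sample_id")
    out <- lapply(split(recs, factor(sample_ids, levels = unique(sample_ids))),
                  function(rs) {
      class_ids <- names(rs[[1L]]$scores)
      m <- do.call(rbind, lapply(rs, function(r) unlist(r$scores[class_ids])))
      score_matrix(m,
                   model_ids = vapply(rs, `[[`, character(1L), "model_id"),
                   class_ids = class_ids)
    })
    return(out)
  }
  stop_usage("unsupported score file extension: .", ext)
}

#' @rdname read_scores
#' @export
write_scores <- function(samples, path) {
  samples <- check_batch(samples)
  if (!length(samples)) stop_data("no samples to write")
  if (is.null(names(samples))) {
    names(samples) <- paste0("S", seq_along(samples))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    class_ids <- colnames(samples[[1L]])
    rows <- lapply(names(samples), function(sid) {
      m <- samples[[sid]]
      data.frame(sample_id = sid, model_id = rownames(m),
                 matrix(sprintf("%.17g", m), nrow(m), ncol(m)),
                 check.names = FALSE, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    names(df) <- c("sample_id", "model_id", class_ids)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "json") {
    recs <- list()
    for (sid in names(samples)) {
      m <- samples[[sid]]
      for (i in seq_len(nrow(m))) {
        recs[[length(recs) + 1L]] <- list(
          sample_id = sid, model_id = rownames(m)[i],
          scores = as.list(stats::setNames(m[i, ], colnames(m))))
      }
    }
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    stop_usage("unsupported score file extension: .", ext)
  }
  invisible(path)
}

#' Read / write two-column label files
#'
#' Labels (truth or predictions) are stored as CSV with columns `sample_id`
#' and `label`.
#'
#' @param path CSV path.
#' @param labels named character vector (names are sample ids) or a
#'   data.frame with `sample_id` and `label` columns.
#' @return `read_labels()`: a named character vector. `write_labels()`: the
#'   path, invisibly.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_data("label file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop_data("label CSV must have sample_id and label columns")
  }
  stats::setNames(df$label, df$sample_id)
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  if (is.data.frame(labels)) {
    df <- labels[c("sample_id", "label")]
  } else {
    df <- data.frame(sample_id = names(labels), label = unname(labels),
                     stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metric report as JSON
#'
#' Emits the proportions, two-decimal percentages (undefined metrics as
#' `"NA"`), and the underlying confusion counts.
#'
#' @param report a [metric_report()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  pct <- lapply(report$percent, function(v) if (is.na(v)) "NA" else v)
  out <- list(
    proportion = report[c("accuracy", "precision", "sensitivity",
                          "specificity", "f1")],
    percent = pct,
    counts = report$counts[c("tp", "tn", "fp", "fn")],
    positive_label = report$counts$positive_label)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
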