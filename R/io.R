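# delimiter by extension: .csv = comma, .tsv = tab
delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") "\t"
  else if (ext == "csv") ","
  else stop(sprintf("unsupported table extension '.%s' (use .csv or .tsv): %s",
                    ext, path), call. = FALSE)
}

read_delim_raw <- function(path) {
  sep <- delim_for(path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.table(path, header = TRUE, sep = sep,
                    colClasses = "character", check.names = FALSE,
                    quote = "\"", comment.char = "", fileEncoding = "UTF-8")
}

# convert character columns to numeric, reporting the first bad cell by
# file line number (header is line 1)
to_numeric_cols <- function(df, cols, path) {
  for (cn in cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad) > 0L || anyNA(df[[cn]]))
      stop(sprintf("non-numeric value in column '%s' of %s (line %d)",
                   cn, path, (if (length(bad) > 0L) bad[1L]
                              else which(is.na(df[[cn]]))[1L]) + 1L),
           call. = FALSE)
    df[[cn]] <- v
  }
  df
}

#' Read a labeled feature-vector table
#'
#' Expects a UTF-8 delimited file (comma for `.csv`, tab for `.tsv`) with
#' header `sample_id,label,f1..fd` and no missing cells.
#'
#' @param path file path.
#' @param class_levels optional explicit class order (default: first
#'   appearance in the label column).
#' @return A [feature_vector_set()].
#' @export
read_feature_table <- function(path, class_levels = NULL) {
  df <- read_delim_raw(path)
  if (ncol(df) < 3L || names(df)[1L] != "sample_id" || names(df)[2L] != "label")
    stop(sprintf("%s: expected header 'sample_id,label,f1..fd'", path),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicate sample id '%s' in %s",
                 df$sample_id[anyDuplicated(df$sample_id)], path),
         call. = FALSE)
  feat_cols <- names(df)[-(1:2)]
  df <- to_numeric_cols(df, feat_cols, path)
  feature_vector_set(as.matrix(df[feat_cols]), labels = df$label,
                     class_levels = class_levels, sample_ids = df$sample_id)
}

#' Write a feature-vector set as a delimited table
#'
#' @param fvs a [feature_vector_set()].
#' @param path destination (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fvs, path) {
  stopifnot(inherits(fvs, "feature_vector_set"))
  d <- ncol(fvs$x)
  out <- data.frame(sample_id = fvs$sample_ids,
                    label = as.character(fvs$labels),
                    fvs$x, check.names = FALSE)
  names(out) <- c("sample_id", "label", paste0("f", seq_len(d)))
  utils::write.table(out, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-model softmax probability table
#'
#' Expects header `sample_id,<class_id_1>..<class_id_k>`. Rows must sum to
#' 1 within `tol` unless `renormalize = TRUE`.
#'
#' @param path file path.
#' @param model_id identifier for the emitting model; defaults to the file
#'   name without extension.
#' @param renormalize rescale off-sum rows instead of rejecting them.
#' @param tol row-sum tolerance.
#' @return A [softmax_table()].
#' @export
read_softmax_table <- function(path, model_id = NULL, renormalize = FALSE,
                               tol = 1e-6) {
  df <- read_delim_raw(path)
  if (ncol(df) < 2L || names(df)[1L] != "sample_id")
    stop(sprintf("%s: expected header 'sample_id,<class ids>'", path),
         call. = FALSE)
  if (is.null(model_id))
    model_id <- tools::file_path_sans_ext(basename(path))
  cls <- names(df)[-1L]
  df <- to_numeric_cols(df, cls, path)
  softmax_table(as.matrix(df[cls]), sample_ids = df$sample_id,
                class_ids = cls, model_id = model_id,
                renormalize = renormalize, tol = tol)
}

#' Write a softmax table
#'
#' @param tab a [softmax_table()].
#' @param path destination (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_softmax_table <- function(tab, path) {
  stopifnot(inherits(tab, "softmax_table"))
  out <- data.frame(sample_id = tab$sample_ids, tab$p, check.names = FALSE)
  names(out) <- c("sample_id", tab$class_ids)
  utils::write.table(out, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a ground-truth label table
#'
#' Expects header `sample_id,label`.
#'
#' @param path file path.
#' @return Data frame with character columns `sample_id` and `label`.
#' @export
read_truth_table <- function(path) {
  df <- read_delim_raw(path)
  if (!identical(names(df)[1:2], c("sample_id", "label")))
    stop(sprintf("%s: expected header 'sample_id,label'", path), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicate sample id in %s", path), call. = FALSE)
  df[c("sample_id", "label")]
}

#' Write a ground-truth label table
#'
#' @param labels character vector of true class labels.
#' @param sample_ids aligned sample identifiers.
#' @param path destination (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(labels, sample_ids, path) {
  stopifnot(length(labels) == length(sample_ids))
  utils::write.table(data.frame(sample_id = sample_ids, label = labels),
                     path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write ensemble predictions
#'
#' Emits `sample_id,predicted,<class_id_1>..<class_id_k>` where the class
#' columns carry the fused probability (or vote-share) rows.
#'
#' @param result an `ensemble_result`.
#' @param path destination (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(result, path) {
  stopifnot(inherits(result, "ensemble_result"))
  out <- data.frame(sample_id = result$sample_ids,
                    predicted = result$predicted,
                    result$fused, check.names = FALSE)
  names(out) <- c("sample_id", "predicted", result$class_ids)
  utils::write.table(out, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an ensemble predictions table
#'
#' @param path file written by [write_predictions()].
#' @return Data frame with `sample_id`, `predicted` and numeric class
#'   columns.
#' @export
read_predictions <- function(path) {
  df <- read_delim_raw(path)
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("sample_id", "predicted")))
    stop(sprintf("%s: expected header 'sample_id,predicted,<class ids>'", path),
         call. = FALSE)
  to_numeric_cols(df, names(df)[-(1:2)], path)
}

#' Write the per-model weights report
#'
#' JSON object keyed by model identifier, each entry carrying `icD`, `bcD`,
#' `FEP` and the normalized ensemble `weight`, in model order.
#'
#' @param fit an [elcdr()] fit.
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_weights_report <- function(fit, path) {
  stopifnot(inherits(fit, "elcdr"))
  rep <- lapply(seq_len(nrow(fit$stats)), function(i)
    list(icD = fit$stats$icD[i], bcD = fit$stats$bcD[i],
         FEP = fit$stats$fep[i], weight = fit$stats$weight[i]))
  names(rep) <- fit$stats$model
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a metrics report
#'
#' JSON report with overall percentages, per-class metrics and the invalid
#' prediction count, plus (optionally) the confusion matrix as a delimited
#' table with class identifiers on both axes.
#'
#' @param metrics result of [classification_metrics()].
#' @param path destination `.json` path.
#' @param cm optional [confusion_matrix()]; when given with `cm_path`, also
#'   written as delimited text.
#' @param cm_path optional `.csv`/`.tsv` destination for the matrix.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path, cm = NULL, cm_path = NULL) {
  out <- list(accuracy = metrics$accuracy, precision = metrics$precision,
              recall = metrics$recall, f1 = metrics$f1,
              per_class = metrics$per_class,
              invalid_count = metrics$invalid_count)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  if (!is.null(cm) && !is.null(cm_path)) {
    df <- data.frame(truth = rownames(cm), unclass(cm), check.names = FALSE)
    utils::write.table(df, cm_path, sep = delim_for(cm_path),
                       row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}
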