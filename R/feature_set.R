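#' Labeled feature-vector set
#'
#' Container for one model's feature embedding of a labeled training set:
#' `t` numeric vectors of common dimension `d`, each carrying one of `k`
#' class labels. This is the input to the separability statistics
#' ([feature_extraction_performance()]) from which ensemble weights are
#' derived.
#'
#' Classes are ordered by first appearance in `labels` unless `class_levels`
#' is supplied. Every class must have at least one member and `k >= 2`.
#'
#' @param x numeric matrix (`t` rows, `d` columns) or object coercible to one.
#' @param labels character vector of length `t`; class identifier per row.
#' @param class_levels optional character vector fixing class order; must
#'   contain every label exactly once.
#' @param sample_ids optional character vector of unique row identifiers;
#'   defaults to `s1..st`.
#' @return An object of class `feature_vector_set`: a list with elements
#'   `x` (the matrix), `labels` (factor with class order as levels), and
#'   `sample_ids`.
#' @examples
#' fvs <- feature_vector_set(rbind(c(0, 0), c(2, 0), c(0, 3), c(0, 5)),
#'                           labels = c("a", "a", "b", "b"))
#' fvs
#' @seealso [compute_centroids()], [feature_extraction_performance()]
#' @export
feature_vector_set <- function(x, labels, class_levels = NULL,
                               sample_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) < 1L || ncol(x) < 1L)
    stop("feature matrix must be numeric with at least one row and column",
         call. = FALSE)
  if (any(!is.finite(x)))
    stop("feature matrix contains non-finite components", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop(sprintf("labels length (%d) must equal vector count (%d)",
                 length(labels), nrow(x)), call. = FALSE)
  if (any(labels == invalid_sentinel()))
    stop(sprintf("class identifier '%s' is reserved", invalid_sentinel()),
         call. = FALSE)
  lev <- if (is.null(class_levels)) unique(labels) else as.character(class_levels)
  if (!setequal(lev, unique(labels)) || anyDuplicated(lev))
    stop("class_levels must list each observed class exactly once",
         call. = FALSE)
  if (length(lev) < 2L)
    stop("at least 2 classes required (k >= 2)", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(x)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(x) || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match the row count", call. = FALSE)
  dimnames(x) <- list(sample_ids, colnames(x))
  structure(list(x = x, labels = factor(labels, levels = lev),
                 sample_ids = sample_ids),
            class = "feature_vector_set")
}

#' @export
print.feature_vector_set <- function(x, ...) {
  cat(sprintf("Feature-vector set: t = %d samples, d = %d, k = %d classes\n",
              nrow(x$x), ncol(x$x), nlevels(x$labels)))
  tab <- table(x$labels)
  cat("  per-class counts:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# sentinel used by the voting strategy for no-plurality samples
invalid_sentinel <- function() "INVALID"

#' Sentinel label for an invalid vote
#'
#' The label recorded when majority voting finds no strict plurality for a
#' sample (including the all-models-disagree case). It is counted as an
#' incorrect prediction by [classification_metrics()].
#'
#' @return The string `"INVALID"`.
#' @export
INVALID_LABEL <- "INVALID"
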