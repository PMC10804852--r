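#' Confusion matrix with an invalid-prediction column
#'
#' Tallies true class (rows) against predicted class (columns) over `k`
#' classes, plus one extra `INVALID` column collecting samples for which the
#' voting strategy found no strict plurality. Row sums equal the per-class
#' ground-truth counts.
#'
#' @param truth character vector of true class labels.
#' @param predicted character vector of predicted labels, aligned with
#'   `truth`; may contain [INVALID_LABEL].
#' @param class_ids optional class order; defaults to first appearance in
#'   `truth`.
#' @return Integer matrix of class `confusion_matrix`, `k` rows by `k + 1`
#'   columns (last column `INVALID`).
#' @examples
#' cm <- confusion_matrix(c("a", "a", "b", "b"), c("a", "b", "b", "INVALID"))
#' cm
#' classification_metrics(cm)
#' @export
confusion_matrix <- function(truth, predicted, class_ids = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must be aligned (same length)", call. = FALSE)
  if (length(truth) == 0L) stop("no samples to evaluate", call. = FALSE)
  if (is.null(class_ids)) class_ids <- unique(truth)
  class_ids <- as.character(class_ids)
  if (any(class_ids == invalid_sentinel()))
    stop(sprintf("class identifier '%s' is reserved", invalid_sentinel()),
         call. = FALSE)
  unknown <- setdiff(truth, class_ids)
  if (length(unknown) > 0L)
    stop(sprintf("unknown true label '%s'", unknown[1L]), call. = FALSE)
  unknown <- setdiff(predicted, c(class_ids, invalid_sentinel()))
  if (length(unknown) > 0L)
    stop(sprintf("unknown predicted label '%s'", unknown[1L]), call. = FALSE)
  m <- table(factor(truth, levels = class_ids),
             factor(predicted, levels = c(class_ids, invalid_sentinel())))
  m <- matrix(as.integer(m), nrow = length(class_ids),
              dimnames = list(truth = class_ids,
                              predicted = c(class_ids, invalid_sentinel())))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = predicted):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' All four metrics are reported as percentages. Accuracy is the diagonal
#' total over all evaluated samples. Precision and recall are averaged over
#' classes; with the default macro averaging each class contributes equally,
#' which makes recall coincide with accuracy on class-balanced test sets.
#' F1 is the harmonic mean of the reported (averaged) precision and recall.
#' A class never predicted contributes precision 0. Predictions in the
#' `INVALID` column are never correct and are excluded from the precision
#' denominators of real classes.
#'
#' @param cm a [confusion_matrix()].
#' @param average `"macro"` (default), `"micro"`, or `"weighted"`
#'   (ground-truth-frequency weights).
#' @return List with `accuracy`, `precision`, `recall`, `f1` (percentages),
#'   `per_class` (data frame of per-class precision/recall/f1 percentages
#'   and support), and `invalid_count`.
#' @export
classification_metrics <- function(cm,
                                   average = c("macro", "micro", "weighted")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  average <- match.arg(average)
  m <- unclass(cm)
  k <- nrow(m)
  total <- sum(m)
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  real <- m[, seq_len(k), drop = FALSE]
  tp <- diag(real)
  pred_n <- colSums(real)      # INVALID column excluded
  true_n <- rowSums(m)
  prec_c <- ifelse(pred_n > 0, tp / pred_n, 0)
  rec_c <- tp / true_n
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  acc <- sum(tp) / total
  if (average == "macro") {
    prec <- mean(prec_c); rec <- mean(rec_c)
  } else if (average == "weighted") {
    wts <- true_n / total
    prec <- sum(wts * prec_c); rec <- sum(wts * rec_c)
  } else { # micro: pooled counts; invalid predictions count as false negatives
    prec <- if (sum(pred_n) > 0) sum(tp) / sum(pred_n) else 0
    rec <- sum(tp) / total
  }
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = 100 * acc, precision = 100 * prec, recall = 100 * rec,
       f1 = 100 * f1,
       per_class = data.frame(class = rownames(m),
                              precision = 100 * prec_c, recall = 100 * rec_c,
                              f1 = 100 * f1_c, support = as.integer(true_n),
                              row.names = NULL),
       invalid_count = as.integer(sum(m[, k + 1L])))
}
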