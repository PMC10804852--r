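#' Per-model softmax probability table
#'
#' One classifier's softmax output over `k` classes for `s` evaluation
#' samples. Every row must sum to 1 within `tol` and lie in \[0, 1\];
#' offending rows are rejected unless `renormalize = TRUE`, in which case
#' rows with positive finite entries are rescaled to sum 1.
#'
#' @param p numeric matrix, `s` rows by `k` probabilities.
#' @param sample_ids character, length `s`, unique.
#' @param class_ids character, length `k`, unique class identifiers;
#'   defaults to `colnames(p)`.
#' @param model_id identifier of the emitting model.
#' @param renormalize rescale rows to sum 1 instead of rejecting them.
#' @param tol row-sum tolerance (default `1e-6`).
#' @return Object of class `softmax_table`: list with `p`, `sample_ids`,
#'   `class_ids`, `model_id`.
#' @export
softmax_table <- function(p, sample_ids = NULL, class_ids = NULL,
                          model_id = "model", renormalize = FALSE,
                          tol = 1e-6) {
  p <- as.matrix(p)
  if (!is.numeric(p) || any(!is.finite(p)))
    stop("probability matrix must be numeric and finite", call. = FALSE)
  if (is.null(class_ids)) class_ids <- colnames(p)
  if (is.null(class_ids))
    stop("class_ids required (or supply column names)", call. = FALSE)
  class_ids <- as.character(class_ids)
  if (length(class_ids) != ncol(p) || anyDuplicated(class_ids))
    stop("class_ids must be unique and match the column count", call. = FALSE)
  if (any(class_ids == invalid_sentinel()))
    stop(sprintf("class identifier '%s' is reserved", invalid_sentinel()),
         call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(p)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(p) || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match the row count", call. = FALSE)
  if (any(p < 0) || any(p > 1 + tol))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  rs <- rowSums(p)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0L) {
    if (!renormalize)
      stop(sprintf(
        "row %d ('%s') sums to %.6g, not 1 (tolerance %g); set renormalize = TRUE to rescale",
        bad[1L], sample_ids[bad[1L]], rs[bad[1L]], tol), call. = FALSE)
    if (any(rs <= 0))
      stop("cannot renormalize a row with nonpositive sum", call. = FALSE)
    p <- p / rs
  }
  dimnames(p) <- list(sample_ids, class_ids)
  structure(list(p = p, sample_ids = sample_ids, class_ids = class_ids,
                 model_id = as.character(model_id)),
            class = "softmax_table")
}

#' @export
print.softmax_table <- function(x, ...) {
  cat(sprintf("Softmax table '%s': %d samples x %d classes (%s)\n",
              x$model_id, nrow(x$p), length(x$class_ids),
              paste(x$class_ids, collapse = ", ")))
  invisible(x)
}

# check n tables share sample ids/order and class ids/order
check_alignment <- function(tables) {
  if (!is.list(tables) || length(tables) == 0L ||
      !all(vapply(tables, inherits, logical(1), "softmax_table")))
    stop("expected a non-empty list of softmax_table objects", call. = FALSE)
  ref <- tables[[1L]]
  first_mismatch <- function(a, b) {
    if (length(a) != length(b)) return(sprintf("count %d vs %d", length(a), length(b)))
    sprintf("'%s'", b[which(a != b)[1L]])
  }
  for (i in seq_along(tables)[-1L]) {
    tb <- tables[[i]]
    if (!identical(tb$class_ids, ref$class_ids))
      stop(sprintf("class identifiers misaligned between '%s' and '%s' (first mismatch: %s)",
                   ref$model_id, tb$model_id,
                   first_mismatch(ref$class_ids, tb$class_ids)), call. = FALSE)
    if (!identical(tb$sample_ids, ref$sample_ids))
      stop(sprintf("sample identifiers misaligned between '%s' and '%s' (first mismatch: %s)",
                   ref$model_id, tb$model_id,
                   first_mismatch(ref$sample_ids, tb$sample_ids)), call. = FALSE)
  }
  invisible(ref)
}

new_ensemble_result <- function(fused, predicted, strategy, ref, weights = NULL) {
  dimnames(fused) <- list(ref$sample_ids, ref$class_ids)
  structure(list(fused = fused, predicted = predicted,
                 sample_ids = ref$sample_ids, class_ids = ref$class_ids,
                 strategy = strategy, weights = weights),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Ensemble result (%s): %d samples, %d classes\n",
              x$strategy, length(x$sample_ids), length(x$class_ids)))
  tab <- table(factor(x$predicted, levels = c(x$class_ids, invalid_sentinel())))
  tab <- tab[tab > 0]
  cat("  predictions:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Highest-probability class of a softmax row
#'
#' Returns the class with the maximum probability; ties are broken toward
#' the lowest class index, deterministically.
#'
#' @param row numeric vector of `k` finite probabilities.
#' @param class_ids character vector of `k` class identifiers.
#' @return A single class identifier.
#' @examples
#' predict_argmax(c(0.2, 0.6, 0.2), c("c1", "c2", "c3")) # "c2"
#' @export
predict_argmax <- function(row, class_ids) {
  row <- as.numeric(row)
  if (length(row) == 0L) stop("empty probability row", call. = FALSE)
  if (any(!is.finite(row))) stop("probability row must be finite", call. = FALSE)
  class_ids <- as.character(class_ids)
  if (length(class_ids) != length(row))
    stop("class_ids must match the row length", call. = FALSE)
  class_ids[which.max(row)]
}

# row-wise argmax with lowest-index tie-break
argmax_rows <- function(p, class_ids) {
  class_ids[max.col(p, ties.method = "first")]
}

#' Weighted softmax fusion
#'
#' The separability-weighted fusion rule: the fused probability row of a
#' sample is the weight-linear combination of the member models' rows,
#' `sf_final = sum_i w_i * sf_i`, and the prediction is the argmax class.
#'
#' @param tables list of `n` [softmax_table()]s with identical sample and
#'   class identifiers, in the same order as `weights`.
#' @param weights numeric weight vector of length `n` (e.g. from
#'   [ensemble_weights()]); must sum to 1 within `1e-6`.
#' @return Object of class `ensemble_result` with elements `fused`
#'   (`s` x `k` matrix), `predicted`, `sample_ids`, `class_ids`,
#'   `strategy`, `weights`.
#' @export
fuse_weighted <- function(tables, weights) {
  ref <- check_alignment(tables)
  weights <- as.numeric(weights)
  if (length(weights) != length(tables))
    stop(sprintf("weight count (%d) must equal table count (%d)",
                 length(weights), length(tables)), call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-6)
    stop(sprintf("weights must sum to 1 (got %.8g)", sum(weights)),
         call. = FALSE)
  fused <- Reduce(`+`, Map(function(tb, w) w * tb$p, tables, weights))
  new_ensemble_result(fused, argmax_rows(fused, ref$class_ids),
                      "elcdr", ref, weights = weights)
}

#' Average-weighting fusion baseline
#'
#' Uniform-weight fusion: the fused row is the arithmetic mean of the member
#' models' rows, `sf_final = sum_i sf_i / n`. Identical to [fuse_weighted()]
#' with all weights `1/n`.
#'
#' @inheritParams fuse_weighted
#' @return An `ensemble_result` (strategy `"average"`).
#' @export
fuse_average <- function(tables) {
  ref <- check_alignment(tables)
  n <- length(tables)
  fused <- Reduce(`+`, lapply(tables, `[[`, "p")) / n
  new_ensemble_result(fused, argmax_rows(fused, ref$class_ids),
                      "average", ref, weights = rep(1 / n, n))
}

#' Majority-voting baseline with invalid-vote handling
#'
#' Each model casts one vote for its argmax class. A sample's prediction is
#' the strict-plurality winner; when the maximum vote count is shared by two
#' or more classes — including the case where every model votes differently —
#' the vote is invalid and the sentinel [INVALID_LABEL] is recorded.
#' Optionally, `fallback = "average"` resolves such samples by uniform
#' average fusion instead.
#'
#' The `fused` field holds the vote-share distribution (votes / n) so the
#' result has the same shape as the other strategies.
#'
#' @inheritParams fuse_weighted
#' @param fallback `"invalid"` (default) records the sentinel;
#'   `"average"` resolves no-plurality samples by average fusion.
#' @return An `ensemble_result` (strategy `"voting"`).
#' @export
fuse_voting <- function(tables, fallback = c("invalid", "average")) {
  fallback <- match.arg(fallback)
  ref <- check_alignment(tables)
  n <- length(tables)
  k <- length(ref$class_ids)
  votes <- vapply(tables, function(tb) max.col(tb$p, ties.method = "first"),
                  integer(nrow(ref$p)))
  votes <- matrix(votes, nrow = nrow(ref$p)) # s x n, class indices
  counts <- t(apply(votes, 1L, tabulate, nbins = k)) # s x k
  top <- apply(counts, 1L, max)
  n_top <- rowSums(counts == top)
  winner <- max.col(counts, ties.method = "first")
  predicted <- ref$class_ids[winner]
  tied <- n_top >= 2L
  if (any(tied)) {
    if (fallback == "average") {
      avg <- fuse_average(tables)
      predicted[tied] <- avg$predicted[tied]
    } else {
      predicted[tied] <- invalid_sentinel()
    }
  }
  new_ensemble_result(counts / n, predicted, "voting", ref)
}
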