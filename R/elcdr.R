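#' Fit separability-derived ensemble weights
#'
#' The core estimator: given each member model's labeled training-set
#' feature embedding, score every model by its feature-extraction
#' performance `FEP = bcD / icD` — mean between-class centroid distance over
#' mean within-class distance — and convert the scores into ensemble weights
#' `w_g = FEP_g / sum(FEP)`. Models whose embeddings separate the classes
#' more cleanly receive proportionally more say when the ensemble fuses
#' softmax outputs (see [predict.elcdr()]).
#'
#' @param features named list of [feature_vector_set()]s, one per member
#'   model (names become model identifiers).
#' @param icd_epsilon optional positive lower clamp on icD for degenerate
#'   (fully collapsed) embeddings; default `NULL` raises an error instead.
#' @return Object of class `elcdr`: list with `stats` (data frame of
#'   model, icD, bcD, fep, weight), `weights` (a `weight_vector`), and
#'   `class_ids`.
#' @examples
#' ens <- generate_ensemble(synth_config(seed = 11))
#' fit <- elcdr(ens$train)
#' summary(fit)
#' pred <- predict(fit, ens$softmax)
#' mean(pred$predicted == ens$truth)
#' @seealso [fuse_weighted()], [fuse_average()], [fuse_voting()]
#' @export
elcdr <- function(features, icd_epsilon = NULL) {
  if (!is.list(features) || length(features) == 0L ||
      !all(vapply(features, inherits, logical(1), "feature_vector_set")))
    stop("features must be a non-empty list of feature_vector_set objects",
         call. = FALSE)
  ids <- names(features)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids))
    stop("features must be a uniquely named list (names = model ids)",
         call. = FALSE)
  lev <- lapply(features, function(f) levels(f$labels))
  if (length(unique(lapply(lev, sort))) != 1L)
    stop("all feature spaces must cover the same classes", call. = FALSE)
  stats_list <- lapply(features, feature_extraction_performance,
                       icd_epsilon = icd_epsilon)
  stats <- data.frame(model = ids,
                      icD = vapply(stats_list, `[[`, numeric(1), "icD"),
                      bcD = vapply(stats_list, `[[`, numeric(1), "bcD"),
                      fep = vapply(stats_list, `[[`, numeric(1), "fep"),
                      row.names = NULL)
  w <- ensemble_weights(stats$fep, model_ids = ids)
  stats$weight <- as.numeric(w)
  structure(list(stats = stats, weights = w, class_ids = lev[[1L]]),
            class = "elcdr")
}

#' @export
print.elcdr <- function(x, digits = 5, ...) {
  cat(sprintf("Separability-weighted ensemble: %d models, %d classes\n",
              nrow(x$stats), length(x$class_ids)))
  df <- x$stats
  df$weight_pct <- 100 * df$weight
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.elcdr <- function(object, ...) {
  structure(list(fit = object), class = "summary.elcdr")
}

#' @export
print.summary.elcdr <- function(x, ...) {
  print(x$fit)
  s <- x$fit$stats
  lead <- s$model[which.max(s$weight)]
  cat(sprintf("Dominant model: %s (weight %.3f); weight ratio max/min = %.3g\n",
              lead, max(s$weight), max(s$weight) / min(s$weight)))
  invisible(x)
}

#' Extract ensemble weights
#'
#' @param object an `elcdr` fit.
#' @param ... unused.
#' @return Named numeric weight vector summing to 1.
#' @export
coef.elcdr <- function(object, ...) {
  stats::setNames(as.numeric(object$weights), names(object$weights))
}

#' Fuse member softmax tables with fitted weights
#'
#' Applies the weighted fusion rule `sf_final = sum_g w_g * sf_g` to the
#' member models' softmax tables and takes the argmax class per sample.
#' Tables are matched to weights by model identifier when `newdata` is
#' named; otherwise positional order is assumed.
#'
#' @param object an [elcdr()] fit.
#' @param newdata named list of [softmax_table()]s, one per fitted model.
#' @param ... unused.
#' @return An `ensemble_result` (see [fuse_weighted()]).
#' @export
predict.elcdr <- function(object, newdata, ...) {
  if (!is.list(newdata) || length(newdata) != nrow(object$stats))
    stop(sprintf("expected %d softmax tables, got %d",
                 nrow(object$stats), length(newdata)), call. = FALSE)
  ids <- names(object$weights)
  if (!is.null(names(newdata)) && !any(names(newdata) == "")) {
    if (!setequal(names(newdata), ids))
      stop("softmax table names do not match fitted model ids", call. = FALSE)
    newdata <- newdata[ids]
  }
  fuse_weighted(newdata, as.numeric(object$weights))
}

#' Plot separability scores and ensemble weights
#'
#' Side-by-side barplots of each member model's feature-extraction
#' performance and its resulting ensemble weight.
#'
#' @param x an `elcdr` fit.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.elcdr <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::barplot(stats::setNames(x$stats$fep, x$stats$model),
                    main = "Feature-extraction performance",
                    ylab = "FEP = bcD / icD", ...)
  graphics::barplot(stats::setNames(100 * x$stats$weight, x$stats$model),
                    main = "Ensemble weight", ylab = "weight (%)", ...)
  invisible(x)
}
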