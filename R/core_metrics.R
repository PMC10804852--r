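#' Euclidean distance between two vectors
#'
#' @param a,b numeric vectors of identical dimension with finite components.
#' @return Nonnegative scalar `sqrt(sum((a - b)^2))`.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop(sprintf("dimension mismatch: length(a) = %d, length(b) = %d",
                 length(a), length(b)), call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("vectors must have finite components", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Class centroids of a feature-vector set
#'
#' The centroid of a class is the arithmetic mean of that class's feature
#' vectors, component-wise.
#'
#' @param fvs a [feature_vector_set()].
#' @return Numeric matrix, `k` rows (one per class, in class order, row
#'   names = class identifiers) by `d` columns.
#' @examples
#' fvs <- feature_vector_set(rbind(c(0, 0), c(2, 2), c(5, 5)),
#'                           labels = c("a", "a", "b"))
#' compute_centroids(fvs) # a -> (1, 1); b -> (5, 5)
#' @export
compute_centroids <- function(fvs) {
  stopifnot(inherits(fvs, "feature_vector_set"))
  counts <- table(fvs$labels)
  if (any(counts == 0L))
    stop(sprintf("class '%s' has no members",
                 names(counts)[counts == 0L][1L]), call. = FALSE)
  cen <- rowsum(fvs$x, fvs$labels) / as.vector(counts[levels(fvs$labels)])
  cen <- cen[levels(fvs$labels), , drop = FALSE]
  rownames(cen) <- levels(fvs$labels)
  cen
}

#' In-category distance (icD)
#'
#' Mean Euclidean distance of every training vector to its own class
#' centroid: the sum over all `t` vectors of the distance to the centroid of
#' the vector's class, divided by `t`. Small icD means tight clusters.
#'
#' @param fvs a [feature_vector_set()].
#' @param centroids optional centroid matrix as returned by
#'   [compute_centroids()]; recomputed from `fvs` when missing.
#' @return Nonnegative scalar.
#' @export
in_category_distance <- function(fvs, centroids = NULL) {
  stopifnot(inherits(fvs, "feature_vector_set"))
  if (is.null(centroids)) centroids <- compute_centroids(fvs)
  centroids <- as.matrix(centroids)
  if (!identical(sort(rownames(centroids)), sort(levels(fvs$labels))) ||
      ncol(centroids) != ncol(fvs$x))
    stop("centroid matrix does not match the feature-vector set", call. = FALSE)
  own <- centroids[as.character(fvs$labels), , drop = FALSE]
  sum(sqrt(rowSums((fvs$x - own)^2))) / nrow(fvs$x)
}

#' Between-categories distance (bcD)
#'
#' Mean Euclidean distance over all `k (k - 1) / 2` unordered pairs of class
#' centroids. Large bcD means well-separated classes.
#'
#' @param centroids centroid matrix (`k >= 2` rows) from [compute_centroids()],
#'   or a [feature_vector_set()] from which centroids are computed.
#' @return Nonnegative scalar.
#' @export
between_categories_distance <- function(centroids) {
  if (inherits(centroids, "feature_vector_set"))
    centroids <- compute_centroids(centroids)
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2L)
    stop("between-categories distance undefined for k < 2", call. = FALSE)
  mean(stats::dist(centroids))
}

#' Feature-extraction performance (FEP) of one model's feature space
#'
#' Summarizes the class-separation geometry of a labeled embedding as the
#' ratio `FEP = bcD / icD`: between-categories centroid distance over
#' in-category distance. A model whose training vectors sit tightly around
#' well-separated class centroids scores high and earns a larger ensemble
#' weight. The ratio is invariant under rigid transforms (rotation +
#' translation) and uniform rescaling of the embedding.
#'
#' Perfectly collapsed clusters (`icD == 0`) make the ratio undefined; by
#' default this raises an error. Supplying `icd_epsilon` instead clamps icD
#' from below, for pipelines that must tolerate degenerate embeddings.
#'
#' @param fvs a [feature_vector_set()].
#' @param icd_epsilon optional positive lower clamp applied to icD; default
#'   `NULL` (degenerate geometry is an error).
#' @return Object of class `separation_stats`: list with `icD`, `bcD`, `fep`.
#' @examples
#' fvs <- feature_vector_set(rbind(c(0, 0), c(2, 0), c(0, 3), c(0, 5)),
#'                           labels = c("a", "a", "b", "b"))
#' feature_extraction_performance(fvs)
#' @export
feature_extraction_performance <- function(fvs, icd_epsilon = NULL) {
  cen <- compute_centroids(fvs)
  icd <- in_category_distance(fvs, cen)
  bcd <- between_categories_distance(cen)
  if (!is.null(icd_epsilon)) {
    stopifnot(is.numeric(icd_epsilon), icd_epsilon > 0)
    icd <- max(icd, icd_epsilon)
  }
  # icD of a fully collapsed set is 0 up to the rounding of the centroid
  # means, so degeneracy is judged relative to the between-class scale
  if (icd == 0 || icd < 1e-12 * bcd)
    stop(paste("degenerate geometry: every vector coincides with its class",
               "centroid (icD = 0); supply icd_epsilon to clamp"),
         call. = FALSE)
  structure(list(icD = icd, bcD = bcd, fep = bcd / icd),
            class = "separation_stats")
}

#' @export
print.separation_stats <- function(x, ...) {
  cat(sprintf("icD = %.6g, bcD = %.6g, FEP = bcD/icD = %.6g\n",
              x$icD, x$bcD, x$fep))
  invisible(x)
}

#' Ensemble weights from feature-extraction performance scores
#'
#' Each model's weight is its FEP divided by the sum of all models' FEPs,
#' so weights are positive and sum to one.
#'
#' @param feps numeric vector of positive, finite FEP values (one per model),
#'   or a list of `separation_stats` objects.
#' @param model_ids optional identifiers; defaults to names of `feps` or
#'   `model1..modeln`.
#' @return Named numeric vector of weights summing to 1, class
#'   `weight_vector`.
#' @examples
#' ensemble_weights(c(vgg11 = 0.881, resnet18 = 2.802, mobilenet = 2.447))
#' @export
ensemble_weights <- function(feps, model_ids = NULL) {
  if (is.list(feps))
    feps <- vapply(feps, function(s) {
      if (inherits(s, "separation_stats")) s$fep else as.numeric(s)
    }, numeric(1))
  if (length(feps) == 0L)
    stop("at least one FEP value required", call. = FALSE)
  if (any(!is.finite(feps)) || any(feps <= 0))
    stop("all FEP values must be finite and > 0", call. = FALSE)
  if (is.null(model_ids))
    model_ids <- if (!is.null(names(feps))) names(feps)
                 else paste0("model", seq_along(feps))
  if (length(model_ids) != length(feps) || anyDuplicated(model_ids))
    stop("model_ids must be unique and match the number of FEP values",
         call. = FALSE)
  w <- feps / sum(feps)
  names(w) <- model_ids
  class(w) <- "weight_vector"
  w
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  print(round(unclass(x), digits), ...)
  invisible(x)
}
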