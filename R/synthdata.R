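# run expr under a local, fixed RNG state; caller's stream is untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# k class-mean directions in d dimensions: mutually orthogonal unit vectors
# when d >= k (QR of a random Gaussian matrix), random unit vectors otherwise
class_directions <- function(k, d) {
  if (d >= k) {
    q <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
    t(q[, seq_len(k), drop = FALSE])
  } else {
    m <- matrix(stats::rnorm(k * d), k, d)
    m / sqrt(rowSums(m^2))
  }
}

#' Generate one synthetic labeled feature space
#'
#' Emulates the training-set embedding of a classifier as `k` isotropic
#' Gaussian clusters: class means are placed along random mutually
#' orthogonal unit directions (random unit directions when `d < k`) scaled
#' by `separation`, and each class's samples are drawn around its mean with
#' standard deviation `spread` per coordinate. Larger `separation / spread`
#' yields a higher feature-extraction-performance score. Output is
#' bit-reproducible for a given argument set.
#'
#' @param k number of classes (>= 2).
#' @param per_class samples drawn per class.
#' @param d feature dimension (>= 1).
#' @param separation scale of the class-mean placement (>= 0; 0 collapses
#'   all means to the origin, leaving only sampling noise between classes).
#' @param spread within-class standard deviation (> 0 for non-degenerate
#'   geometry; 0 is allowed and collapses every sample onto its class mean).
#' @param seed integer seed; the caller's RNG state is preserved.
#' @param class_ids optional class identifiers (default `c1..ck`).
#' @param id_prefix prefix for generated sample identifiers.
#' @param means optional `k` x `d` matrix of class means, overriding the
#'   seeded placement — used to draw several splits from one embedding.
#' @return A [feature_vector_set()].
#' @examples
#' fvs <- generate_feature_space(k = 3, per_class = 10, d = 4,
#'                               separation = 5, spread = 1, seed = 1)
#' feature_extraction_performance(fvs)
#' @export
generate_feature_space <- function(k, per_class, d, separation, spread, seed,
                                   class_ids = NULL, id_prefix = "s",
                                   means = NULL) {
  stopifnot(per_class >= 1, separation >= 0, spread >= 0)
  if (d < 1 || k < 2)
    stop("need feature dimension d >= 1 and class count k >= 2", call. = FALSE)
  if (is.null(class_ids)) class_ids <- paste0("c", seq_len(k))
  stopifnot(length(class_ids) == k)
  if (!is.null(means)) stopifnot(nrow(means) == k, ncol(means) == d)
  with_seed(seed, {
    if (is.null(means)) means <- separation * class_directions(k, d)
    x <- means[rep(seq_len(k), each = per_class), , drop = FALSE] +
      matrix(stats::rnorm(k * per_class * d, sd = spread), k * per_class, d)
    feature_vector_set(x, labels = rep(class_ids, each = per_class),
                       class_levels = class_ids,
                       sample_ids = paste0(id_prefix, seq_len(k * per_class)))
  })
}

#' Centroid-distance softmax for synthetic evaluation samples
#'
#' Stands in for a trained classifier's softmax head: the probability a
#' sample belongs to a class decays exponentially with the Euclidean
#' distance from the sample to that class's training centroid,
#' `p_j` proportional to `exp(-dist(x, cen_j) / temperature)`, normalized to
#' sum 1. Lower temperatures sharpen the rows toward the nearest centroid.
#' Deterministic given its inputs. This simulated classifier ties
#' classification quality to feature-space separability by construction.
#'
#' @param features a [feature_vector_set()] of evaluation samples.
#' @param centroids centroid matrix from [compute_centroids()] on the
#'   training split of the same model's feature space.
#' @param temperature positive softness parameter (distance units).
#' @param model_id identifier stamped on the resulting table.
#' @return A [softmax_table()] over the centroid classes.
#' @export
simulate_softmax <- function(features, centroids, temperature = 1,
                             model_id = "model") {
  stopifnot(inherits(features, "feature_vector_set"))
  centroids <- as.matrix(centroids)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be > 0", call. = FALSE)
  if (ncol(centroids) != ncol(features$x))
    stop(sprintf("dimension mismatch: centroids d = %d, features d = %d",
                 ncol(centroids), ncol(features$x)), call. = FALSE)
  d2 <- outer(rowSums(features$x^2), rep(1, nrow(centroids))) -
    2 * features$x %*% t(centroids) +
    outer(rep(1, nrow(features$x)), rowSums(centroids^2))
  dist_mat <- sqrt(pmax(d2, 0))
  z <- -dist_mat / temperature
  z <- z - apply(z, 1L, max)            # log-sum-exp stabilization
  p <- exp(z) / rowSums(exp(z))
  softmax_table(p, sample_ids = features$sample_ids,
                class_ids = rownames(centroids), model_id = model_id)
}

#' Synthetic-ensemble configuration
#'
#' Bundles the shape of a simulated multi-model experiment: shared class
#' structure and sample counts, plus one (separation, spread, temperature)
#' triple per simulated model. Defaults model a three-member ensemble of one
#' strong, one middling and one weak feature extractor over four classes.
#'
#' @param k class count.
#' @param per_class_train,per_class_test samples per class in the training
#'   and evaluation splits (drawn independently, so per-class counts are
#'   exact in both).
#' @param d feature dimension.
#' @param model_specs data frame with columns `model_id`, `separation`,
#'   `spread`, `temperature` — one row per simulated model.
#' @param seed integer master seed; all draws derive from it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(k = 4, per_class_train = 50, per_class_test = 50,
                         d = 16,
                         model_specs = data.frame(
                           model_id = c("modelA", "modelB", "modelC"),
                           separation = c(6, 3, 1),
                           spread = 1,
                           temperature = 1),
                         seed = 1) {
  stopifnot(k >= 2, per_class_train >= 1, per_class_test >= 1, d >= 1,
            is.data.frame(model_specs), nrow(model_specs) >= 1,
            all(c("model_id", "separation", "spread", "temperature") %in%
                  names(model_specs)),
            !anyDuplicated(model_specs$model_id),
            all(model_specs$separation >= 0), all(model_specs$spread > 0),
            all(model_specs$temperature > 0))
  structure(list(k = k, per_class_train = per_class_train,
                 per_class_test = per_class_test, d = d,
                 model_specs = model_specs, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a full synthetic multi-model ensemble
#'
#' Produces, per simulated model, a labeled training feature space and a
#' matched softmax table for a shared evaluation split, plus the shared
#' ground-truth labels. Every model sees the same evaluation samples (same
#' identifiers and true classes) through its own embedding; its softmax rows
#' come from [simulate_softmax()] against its own training centroids, so
#' better-separated models produce more confident, more accurate tables.
#' When `dir` is given, all tables are also written as delimited files along
#' with a JSON manifest recording the configuration and seed.
#'
#' @param config a [synth_config()].
#' @param dir optional directory to write fixture files into (created if
#'   missing): `features_<model_id>.csv`, `softmax_<model_id>.csv`,
#'   `truth.csv`, `manifest.json`.
#' @return List with `train` (named list of [feature_vector_set()]s),
#'   `softmax` (named list of [softmax_table()]s), `truth` (character
#'   labels), `sample_ids`, `class_ids`, and `files` (named paths when `dir`
#'   was given, otherwise `NULL`).
#' @examples
#' ens <- generate_ensemble(synth_config(seed = 7))
#' fit <- elcdr(ens$train)
#' coef(fit)
#' @export
generate_ensemble <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  specs <- config$model_specs
  class_ids <- paste0("c", seq_len(config$k))
  truth <- rep(class_ids, each = config$per_class_test)
  test_ids <- paste0("t", seq_len(length(truth)))
  train <- list(); softmax <- list()
  for (i in seq_len(nrow(specs))) {
    mid <- as.character(specs$model_id[i])
    # disjoint per-model, per-split seeds derived from the master seed;
    # both splits share one class-mean placement (one embedding per model)
    seed_means <- config$seed + 10000L * i
    seed_train <- seed_means + 3000L
    seed_test <- seed_means + 6000L
    means <- with_seed(seed_means,
                       specs$separation[i] * class_directions(config$k, config$d))
    train[[mid]] <- generate_feature_space(
      config$k, config$per_class_train, config$d,
      specs$separation[i], specs$spread[i], seed_train,
      class_ids = class_ids, id_prefix = "r", means = means)
    test_fvs <- generate_feature_space(
      config$k, config$per_class_test, config$d,
      specs$separation[i], specs$spread[i], seed_test,
      class_ids = class_ids, id_prefix = "t", means = means)
    softmax[[mid]] <- simulate_softmax(test_fvs,
                                       compute_centroids(train[[mid]]),
                                       specs$temperature[i], model_id = mid)
  }
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(0)
    for (mid in names(train)) {
      fp <- file.path(dir, paste0("features_", mid, ".csv"))
      write_feature_table(train[[mid]], fp)
      sp <- file.path(dir, paste0("softmax_", mid, ".csv"))
      write_softmax_table(softmax[[mid]], sp)
      files[paste0("features_", mid)] <- fp
      files[paste0("softmax_", mid)] <- sp
    }
    tp <- file.path(dir, "truth.csv")
    write_truth_table(truth, test_ids, tp)
    files["truth"] <- tp
    mp <- file.path(dir, "manifest.json")
    jsonlite::write_json(
      list(generator = "elcdr::generate_ensemble",
           k = config$k, d = config$d,
           per_class_train = config$per_class_train,
           per_class_test = config$per_class_test,
           seed = config$seed,
           models = specs),
      mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files["manifest"] <- mp
  }
  list(train = train, softmax = softmax, truth = truth,
       sample_ids = test_ids, class_ids = class_ids, files = files)
}
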