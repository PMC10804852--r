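# Naive, loop-based oracles kept deliberately independent of the package's
# vectorized implementations.

naive_dist <- function(a, b) {
  s <- 0
  for (j in seq_along(a)) s <- s + (a[j] - b[j])^2
  as.numeric(sqrt(s))
}

naive_centroids <- function(x, labels) {
  lev <- unique(labels)
  cen <- matrix(0, length(lev), ncol(x), dimnames = list(lev, NULL))
  for (p in lev) {
    acc <- rep(0, ncol(x)); m <- 0
    for (i in seq_len(nrow(x))) if (labels[i] == p) {
      acc <- acc + x[i, ]; m <- m + 1
    }
    cen[p, ] <- acc / m
  }
  cen
}

naive_icd <- function(x, labels) {
  cen <- naive_centroids(x, labels)
  tot <- 0
  for (i in seq_len(nrow(x))) tot <- tot + naive_dist(cen[labels[i], ], x[i, ])
  tot / nrow(x)
}

naive_bcd <- function(cen) {
  k <- nrow(cen); tot <- 0; npair <- 0
  for (p in seq_len(k - 1)) for (q in (p + 1):k) {
    tot <- tot + naive_dist(cen[p, ], cen[q, ]); npair <- npair + 1
  }
  tot / npair
}

naive_fuse <- function(mats, weights) {
  out <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
  for (i in seq_along(mats))
    for (r in seq_len(nrow(out)))
      for (cc in seq_len(ncol(out)))
        out[r, cc] <- out[r, cc] + weights[i] * mats[[i]][r, cc]
  out
}

naive_argmax <- function(row) {
  best <- 1
  for (j in seq_along(row)) if (row[j] > row[best]) best <- j
  best
}

naive_confusion <- function(truth, predicted, class_ids) {
  cols <- c(class_ids, "INVALID")
  m <- matrix(0L, length(class_ids), length(cols),
              dimnames = list(class_ids, cols))
  for (i in seq_along(truth))
    m[truth[i], predicted[i]] <- m[truth[i], predicted[i]] + 1L
  m
}

# random fixture builders --------------------------------------------------

random_fvs <- function(t_max = 50, d_max = 8, k_max = 5) {
  k <- sample(2:k_max, 1)
  d <- sample(1:d_max, 1)
  # at least one member per class and one class with >= 2 members (so the
  # in-category distance is almost surely positive), t <= t_max
  counts <- rep(1L, k)
  counts[1] <- 2L
  extra <- sample(0:(t_max - k - 1), 1)
  if (extra > 0) {
    add <- table(factor(sample(k, extra, replace = TRUE), levels = 1:k))
    counts <- counts + as.integer(add)
  }
  labels <- rep(paste0("k", seq_len(k)), times = counts)
  x <- matrix(rnorm(sum(counts) * d, sd = 2), sum(counts), d)
  feature_vector_set(x, labels)
}

random_softmax_mats <- function(n, s, k) {
  lapply(seq_len(n), function(i) {
    m <- matrix(rexp(s * k), s, k)
    m / rowSums(m)
  })
}

random_tables <- function(n, s, k, ids = NULL) {
  mats <- random_softmax_mats(n, s, k)
  class_ids <- paste0("c", seq_len(k))
  sample_ids <- paste0("s", seq_len(s))
  lapply(seq_len(n), function(i)
    softmax_table(mats[[i]], sample_ids, class_ids,
                  model_id = if (is.null(ids)) paste0("m", i) else ids[i]))
}

# 1-D two-class set whose icD and bcD equal the requested values exactly:
# class a = {-icd, +icd} (centroid 0), class b = {bcd - icd, bcd + icd}
fvs_with_geometry <- function(icd, bcd) {
  feature_vector_set(matrix(c(-icd, icd, bcd - icd, bcd + icd), ncol = 1),
                     labels = c("a", "a", "b", "b"))
}

# published per-crop separability statistics for the three CNN backbones
reference_stats <- function() separability_reference()
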