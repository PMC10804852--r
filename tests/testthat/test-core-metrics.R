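test_that("euclidean_distance matches closed forms and the loop oracle", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 1), c(1, 1)), 0)
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(euclidean_distance(a, b), naive_dist(a, b),
                 tolerance = 1e-12)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
  }
  expect_error(euclidean_distance(1:3, 1:4), "dimension mismatch")
  expect_error(euclidean_distance(c(1, NA), c(1, 2)), "finite")
})

test_that("centroids are per-class means", {
  f1 <- feature_vector_set(rbind(c(2, 7), c(0, 0), c(2, 2)),
                           labels = c("solo", "pair", "pair"))
  cen <- compute_centroids(f1)
  expect_equal(cen["solo", ], c(2, 7), ignore_attr = TRUE)
  expect_equal(cen["pair", ], c(1, 1), ignore_attr = TRUE)
  set.seed(7)
  x <- matrix(rnorm(15 * 4), 15, 4)
  labels <- rep(c("a", "b", "c"), each = 5)
  fvs <- feature_vector_set(x, labels)
  expect_equal(unname(compute_centroids(fvs)),
               unname(naive_centroids(x, labels)), tolerance = 1e-12)
})

test_that("class order follows first appearance unless class_levels is given", {
  fvs <- feature_vector_set(matrix(1:4, 4, 1), c("z", "a", "z", "a"))
  expect_identical(levels(fvs$labels), c("z", "a"))
  expect_identical(rownames(compute_centroids(fvs)), c("z", "a"))
  fvs2 <- feature_vector_set(matrix(1:4, 4, 1), c("z", "a", "z", "a"),
                             class_levels = c("a", "z"))
  expect_identical(levels(fvs2$labels), c("a", "z"))
})

test_that("in-category distance averages distances to own centroid", {
  fvs <- feature_vector_set(rbind(c(0, 0), c(2, 0), c(0, 3), c(0, 5)),
                            labels = c("A", "A", "B", "B"))
  expect_equal(in_category_distance(fvs), 1.0)
  # every vector at its centroid
  tight <- feature_vector_set(rbind(c(1, 1), c(1, 1), c(4, 4)),
                              labels = c("a", "a", "b"))
  expect_equal(in_category_distance(tight), 0)
  set.seed(11)
  x <- matrix(rnorm(30 * 3), 30, 3)
  labels <- sample(rep(c("a", "b", "c"), 10))
  fvs <- feature_vector_set(x, labels)
  expect_equal(in_category_distance(fvs), naive_icd(x, labels),
               tolerance = 1e-12)
  bad_cen <- compute_centroids(fvs)[, 1:2]
  expect_error(in_category_distance(fvs, bad_cen), "does not match")
})

test_that("between-categories distance averages all centroid pairs", {
  expect_equal(between_categories_distance(rbind(c(0, 0), c(3, 4))), 5)
  tri <- 2 * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(between_categories_distance(tri), 2, tolerance = 1e-12)
  set.seed(5)
  cen <- matrix(rnorm(4 * 3), 4, 3)
  expect_equal(between_categories_distance(cen), naive_bcd(cen),
               tolerance = 1e-12)
  expect_error(between_categories_distance(matrix(1:3, 1, 3)),
               "undefined for k < 2")
})

test_that("FEP is bcD/icD with a degenerate-geometry guard", {
  # geometry with icD == bcD gives ratio 1
  unit <- fvs_with_geometry(1, 1)
  s <- feature_extraction_performance(unit)
  expect_equal(s$fep, 1.0)
  expect_equal(s$icD, 1.0)
  expect_equal(s$bcD, 1.0)
  # collapsed clusters: error by default, clamped when epsilon supplied
  collapsed <- feature_vector_set(rbind(c(0, 0), c(0, 0), c(5, 5)),
                                  labels = c("a", "a", "b"))
  expect_error(feature_extraction_performance(collapsed), "degenerate")
  clamped <- feature_extraction_performance(collapsed, icd_epsilon = 1e-6)
  expect_equal(clamped$icD, 1e-6)
  expect_equal(clamped$fep, clamped$bcD / 1e-6)
})

test_that("FEP reproduces the reference CNN separability statistics", {
  ref <- reference_stats()
  for (i in seq_len(nrow(ref))) {
    s <- feature_extraction_performance(fvs_with_geometry(ref$icD[i],
                                                          ref$bcD[i]))
    expect_equal(s$icD, ref$icD[i], tolerance = 1e-12)
    expect_equal(s$bcD, ref$bcD[i], tolerance = 1e-12)
    expect_equal(s$fep, ref$FEP[i], tolerance = 5e-6)
  }
})

test_that("ensemble weights normalize FEPs and preserve their order", {
  w <- ensemble_weights(c(0.880997, 2.801886, 2.447378),
                        c("VGG11", "ResNet18", "MobileNet_v3"))
  expect_equal(as.numeric(w), c(0.14371, 0.45706, 0.39923), tolerance = 5e-5)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_equal(as.numeric(ensemble_weights(rep(2.5, 3))), rep(1, 3) / 3)
  set.seed(3)
  for (i in 1:25) {
    feps <- rexp(sample(1:6, 1)) + 1e-3
    w <- ensemble_weights(feps)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w > 0))
    expect_identical(order(as.numeric(w)), order(feps))
  }
  expect_error(ensemble_weights(numeric(0)), "at least one")
  expect_error(ensemble_weights(c(1, 0)), "> 0")
  expect_error(ensemble_weights(c(1, Inf)), "finite")
})

test_that("separability statistics are rigid-transform invariant and scale covariant", {
  set.seed(19)
  for (i in 1:10) {
    fvs <- random_fvs()
    d <- ncol(fvs$x)
    s0 <- feature_extraction_performance(fvs)
    # random rotation + translation
    q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
    shift <- rnorm(d, sd = 5)
    moved <- feature_vector_set(sweep(fvs$x %*% q, 2, shift, "+"),
                                as.character(fvs$labels))
    s1 <- feature_extraction_performance(moved)
    expect_equal(s1$icD, s0$icD, tolerance = 1e-9)
    expect_equal(s1$bcD, s0$bcD, tolerance = 1e-9)
    expect_equal(s1$fep, s0$fep, tolerance = 1e-9)
    # uniform positive scaling
    c0 <- runif(1, 0.1, 10)
    scaled <- feature_vector_set(c0 * fvs$x, as.character(fvs$labels))
    s2 <- feature_extraction_performance(scaled)
    expect_equal(s2$icD, c0 * s0$icD, tolerance = 1e-9)
    expect_equal(s2$bcD, c0 * s0$bcD, tolerance = 1e-9)
    expect_equal(s2$fep, s0$fep, tolerance = 1e-9)
  }
})

test_that("moving class means apart strictly increases FEP", {
  set.seed(23)
  x <- matrix(rnorm(40 * 2), 40, 2)
  labels <- rep(c("a", "b"), each = 20)
  seps <- c(0.5, 1, 2, 4, 8)
  feps <- vapply(seps, function(s) {
    shifted <- x
    shifted[labels == "b", 1] <- shifted[labels == "b", 1] + s
    feature_extraction_performance(
      feature_vector_set(shifted, labels))$fep
  }, numeric(1))
  expect_true(all(diff(feps) > 0))
})

test_that("invalid feature-vector sets are rejected", {
  expect_error(feature_vector_set(matrix(c(1, NA), 2, 1), c("a", "b")),
               "non-finite")
  expect_error(feature_vector_set(matrix(1:4, 2, 2), c("a", "a")),
               "at least 2 classes")
  expect_error(feature_vector_set(matrix(1:4, 2, 2), c("a")),
               "labels length")
  expect_error(feature_vector_set(matrix(1:4, 2, 2), c("a", "INVALID")),
               "reserved")
})
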