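test_that("within-class cost is the normalized mean distance to the center", {
  # all samples at the center
  expect_identical(within_class_cost(c(1, 2), rbind(c(1, 2), c(1, 2))), 0)
  # single sample at distance 2
  expect_equal(within_class_cost(c(0, 0), rbind(c(0, 2))), 2)
  # two 1-D samples at 0 and 4, center 1: (1 + 3) / 2
  expect_equal(within_class_cost(1, matrix(c(0, 4), 2, 1)), 2)
  # normalization: duplicating the samples leaves the cost unchanged
  set.seed(1)
  x <- matrix(rnorm(20), 10, 2)
  z <- rnorm(2)
  expect_equal(within_class_cost(z, x), within_class_cost(z, rbind(x, x)))
  expect_error(within_class_cost(c(0, 0, 0), x), "dimension")
})

test_that("k-means objective matches a brute-force double loop", {
  expect_identical(kmeans_objective(rbind(c(1, 0), c(0, 1)),
                                    rbind(c(1, 1), c(2, 2)),
                                    rbind(c(1, 1), c(2, 2))), 0)
  # one sample, one center, distance 3 -> squared norm 9
  expect_equal(kmeans_objective(matrix(1), matrix(c(0, 0), 1),
                                matrix(c(0, 3), 1)), 9)
  # independent loop-based oracle on random instances
  for (s in 1:50) {
    set.seed(s)
    n <- sample(5:12, 1); k <- sample(2:4, 1); d <- sample(1:3, 1)
    x <- matrix(rnorm(n * d), n, d)
    z <- matrix(rnorm(k * d), k, d)
    a <- matrix(0, n, k)
    a[cbind(seq_len(n), sample(k, n, replace = TRUE))] <- 1
    oracle <- 0
    for (i in seq_len(n)) for (j in seq_len(k)) {
      oracle <- oracle + a[i, j] * sum((x[i, ] - z[j, ])^2)
    }
    expect_equal(kmeans_objective(a, x, z), oracle, tolerance = 1e-9)
  }
  expect_error(kmeans_objective(rbind(c(1, 1)), matrix(0, 1, 1),
                                matrix(0, 2, 1)), "exactly one 1")
})

test_that("class mean agrees with an independent summation oracle", {
  expect_identical(class_mean(rbind(c(0, 0), c(2, 2))), c(1, 1))
  expect_identical(class_mean(rbind(c(3.5, -1))), c(3.5, -1))
  set.seed(4)
  x <- matrix(rnorm(30), 10, 3)
  manual <- c(sum(x[, 1]), sum(x[, 2]), sum(x[, 3])) / 10
  expect_equal(class_mean(x), manual)
  expect_error(class_mean(x[0, , drop = FALSE]), "nonempty")
})

test_that("degenerate class collapses every trained center onto the point", {
  x <- matrix(rep(c(2, -3), each = 8), 8, 2)
  lm <- labeled_matrix(rbind(x, x + 10), rep(c("A", "B"), each = 8))
  m <- train_class_centers(lm, 1:2, abc_config(max_cycles = 5, seed = 1))
  expect_true(all(abs(sweep(m$centers_by_class$A, 2, c(2, -3))) < 1e-6))
  expect_true(all(abs(sweep(m$centers_by_class$B, 2, c(12, 7))) < 1e-6))
})

test_that("trained centers track the class location on separated Gaussians", {
  set.seed(8)
  n <- 40
  x <- rbind(matrix(rnorm(2 * n, 0, 0.1), n, 2),
             matrix(rnorm(2 * n, 3, 0.1), n, 2))
  lm <- labeled_matrix(x, rep(c("A", "B"), each = n))
  m <- train_class_centers(lm, 1:2, abc_config(seed = 2))
  for (cls in c("A", "B")) {
    mu <- class_mean(lm$features[lm$labels == cls, ])
    expect_lt(sqrt(sum((m$best_by_class[[cls]]$position - mu)^2)), 0.2)
    expect_identical(ncol(m$centers_by_class[[cls]]), 2L)
  }
})

test_that("abc best cost approaches the geometric-median optimum", {
  # the geometric median minimizes the summed plain distance, i.e. the
  # within-class cost; the trained best center should not do worse
  for (s in 1:5) {
    set.seed(s)
    d <- sample(1:3, 1)
    x <- matrix(rnorm(30 * d, sd = 2), 30, d)
    lm <- labeled_matrix(cbind(x), rep("A", 30), class_set = "A")
    m <- train_class_centers(lm, seq_len(d), abc_config(seed = s))
    gm <- geometric_median(x)
    expect_lte(m$best_by_class$A$cost, within_class_cost(gm, x) + 1e-2)
  }
})

test_that("duplicated training data leaves trained costs unchanged", {
  set.seed(10)
  x <- matrix(rnorm(40), 20, 2)
  lm1 <- labeled_matrix(x, rep(c("A", "B"), 10))
  lm2 <- labeled_matrix(rbind(x, x), rep(rep(c("A", "B"), 10), 2))
  # normalization by the sample count makes the cost itself scale-free
  for (s in 1:10) {
    z <- rnorm(2)
    xa <- lm1$features[lm1$labels == "A", ]
    expect_equal(within_class_cost(z, xa), within_class_cost(z, rbind(xa, xa)),
                 tolerance = 1e-12)
  }
  cfg <- abc_config(max_cycles = 40, seed = 6)
  m1 <- train_class_centers(lm1, 1:2, cfg)
  m2 <- train_class_centers(lm2, 1:2, cfg)
  # same box, same seed, same (scale-free) cost: the trained models agree
  # up to floating-point summation order in the duplicated sums
  expect_equal(m1$costs_by_class, m2$costs_by_class, tolerance = 1e-9)
  expect_equal(m1$centers_by_class, m2$centers_by_class, tolerance = 1e-6)
})

test_that("nearest-food classification honors distance and tie-breaks", {
  m <- structure(list(
    centers_by_class = list(A = rbind(c(0, 0), c(0.5, 0)),
                            B = rbind(c(2, 0), c(3, 0))),
    costs_by_class = list(A = c(0.1, 0.2), B = c(0.1, 0.2)),
    best_by_class = list(A = list(position = c(0, 0), cost = 0.1),
                         B = list(position = c(2, 0), cost = 0.1)),
    feature_indices = 1:2, class_set = c("A", "B")),
    class = "class_center_model")
  # exactly on a class-A center
  expect_identical(classify_nearest_food(m, c(0, 0)), "A")
  # equidistant between A at 0.5 and B at 2 -> midpoint 1.25: tie goes to A
  expect_identical(classify_nearest_food(m, c(1.25, 0)), "A")
  # best-only mode uses one center per class
  expect_identical(classify_nearest_food(m, c(1.4, 0), centers = "best"), "B")
  expect_error(classify_nearest_food(m, c(1, 2, 3)), "columns")
})

test_that("classification is invariant to center permutation within a class", {
  set.seed(12)
  lm <- separable_fixture(n = 25, seed = 12)
  m <- train_class_centers(lm, 1:2, abc_config(max_cycles = 60, seed = 3))
  q <- matrix(rnorm(40, 1.5, 1.5), 20, 2)
  p1 <- classify_nearest_food(m, q)
  m2 <- m
  m2$centers_by_class$A <- m$centers_by_class$A[sample(nrow(m$centers_by_class$A)), ]
  m2$centers_by_class$B <- m$centers_by_class$B[sample(nrow(m$centers_by_class$B)), ]
  expect_identical(classify_nearest_food(m2, q), p1)
})

test_that("held-out accuracy is high on the separable Gaussian fixture", {
  fx <- generate_dataset(synth_spec(n_per_class = c(60, 60),
                                    n_informative = 2, n_noise = 0,
                                    class_separation = 6, seed = 21))
  sp <- stratified_split(fx$data, 0.75, seed = 2)
  m <- train_class_centers(sp$train, 1:2, abc_config(seed = 4))
  pred <- classify_nearest_food(m, sp$test$features)
  expect_gt(mean(pred == sp$test$labels), 0.95)
})
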