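test_that("confusion counts follow the positive-class convention", {
  expect_identical(unclass(confusion(rep("p", 5), rep("p", 5), "p"))[1:4],
                   list(tp = 5L, fp = 0L, fn = 0L, tn = 0L))
  cm <- confusion(c("p", "p", "n"), c("n", "n", "p"), "p")
  expect_identical(c(cm$tp, cm$tn), c(0L, 0L))
  expect_identical(c(cm$fn, cm$fp), c(2L, 1L))
  # loop oracle on random binary label vectors
  for (s in 1:20) {
    set.seed(s)
    yt <- sample(c("p", "n"), 30, replace = TRUE)
    yp <- sample(c("p", "n"), 30, replace = TRUE)
    cm <- confusion(yt, yp, "p")
    tp <- fp <- fn <- tn <- 0L
    for (i in 1:30) {
      if (yt[i] == "p" && yp[i] == "p") tp <- tp + 1L
      if (yt[i] == "n" && yp[i] == "p") fp <- fp + 1L
      if (yt[i] == "p" && yp[i] == "n") fn <- fn + 1L
      if (yt[i] == "n" && yp[i] == "n") tn <- tn + 1L
    }
    expect_identical(unclass(cm)[1:4],
                     list(tp = tp, fp = fp, fn = fn, tn = tn))
    expect_identical(cm$tp + cm$fp + cm$fn + cm$tn, 30L)
  }
  expect_error(confusion(c("a", "b"), c("c", "a"), "a"), "binary")
})

test_that("metrics reproduce the defining ratios and flag zero denominators", {
  cm <- structure(list(tp = 97L, fp = 12L, fn = 3L, tn = 88L,
                       positive_class = "p"), class = "confusion_matrix")
  m <- metrics(cm)
  expect_equal(m$sensitivity, 0.97)
  expect_equal(m$specificity, 0.88)
  expect_equal(m$accuracy, 0.925)
  expect_equal(m$ppv, 97 / 109)
  expect_equal(m$npv, 88 / 91)
  expect_identical(m$undefined, character(0))
  # no positives predicted: PPV undefined, not zero
  cm0 <- confusion(c("p", "n"), c("n", "n"), "p")
  m0 <- metrics(cm0)
  expect_true(is.na(m0$ppv))
  expect_identical(m0$undefined, "ppv")
  expect_true(is.na(metrics(confusion(rep("n", 4), rep("n", 4), "p",
                                      class_set = c("n", "p")))$sensitivity))
  # perfect predictions: every metric is 1
  mp <- metrics(confusion(c("p", "p", "n"), c("p", "p", "n"), "p"))
  expect_identical(unlist(mp[c("accuracy", "sensitivity", "specificity",
                               "ppv", "npv")], use.names = FALSE),
                   rep(1, 5))
})

test_that("metrics agree with exact hand arithmetic on random matrices", {
  for (s in 1:100) {
    set.seed(s)
    v <- as.integer(sample(0:30, 4, replace = TRUE))
    if (sum(v) == 0) v[1] <- 1L
    cm <- structure(list(tp = v[1], fp = v[2], fn = v[3], tn = v[4],
                         positive_class = "p"), class = "confusion_matrix")
    m <- metrics(cm)
    expect_identical(m$accuracy, (v[1] + v[4]) / sum(v))
    expect_identical(m$sensitivity,
                     if (v[1] + v[3] == 0L) NA_real_ else v[1] / (v[1] + v[3]))
    expect_identical(m$specificity,
                     if (v[4] + v[2] == 0L) NA_real_ else v[4] / (v[4] + v[2]))
    expect_identical(m$ppv,
                     if (v[1] + v[2] == 0L) NA_real_ else v[1] / (v[1] + v[2]))
    expect_identical(m$npv,
                     if (v[4] + v[3] == 0L) NA_real_ else v[4] / (v[4] + v[3]))
  }
})

test_that("metrics and confusion are invariant under sample reordering", {
  set.seed(5)
  yt <- sample(c("p", "n"), 40, replace = TRUE)
  yp <- sample(c("p", "n"), 40, replace = TRUE)
  perm <- sample(40)
  expect_identical(metrics(confusion(yt, yp, "p")),
                   metrics(confusion(yt[perm], yp[perm], "p")))
})

test_that("stratified folds partition the data and preserve proportions", {
  labels <- rep(c("A", "B"), c(60, 40))
  for (k in c(2, 5, 10)) {
    for (s in 1:5) {
      folds <- stratified_kfold(labels, k, seed = s)
      val <- lapply(folds, `[[`, "validation")
      expect_identical(sort(unlist(val)), 1:100)      # partition
      expect_identical(anyDuplicated(unlist(val)), 0L) # disjoint
      for (f in folds) {
        expect_identical(sort(c(f$train, f$validation)), 1:100)
        na <- sum(labels[f$validation] == "A")
        expect_lte(abs(na - 60 / k), 1)
        expect_lte(abs(length(f$validation) - na - 40 / k), 1)
      }
    }
  }
  # n = 100, k = 10: every validation fold has exactly 10 samples
  folds <- stratified_kfold(labels, 10, seed = 1)
  expect_true(all(vapply(folds, function(f) length(f$validation),
                         integer(1)) == 10L))
  expect_identical(stratified_kfold(labels, 5, seed = 9),
                   stratified_kfold(labels, 5, seed = 9))
  expect_error(stratified_kfold(rep(c("A", "B"), c(96, 4)), 10), "fewer than")
})

test_that("cross-validation is perfect on separable data and runs leave-one-out", {
  sep <- separable_fixture(n = 20, seed = 3)
  for (k in c(2, 5)) {
    cv <- cross_validate(sep, k = k, seed = 2)
    expect_identical(cv$mean$accuracy, 1)
  }
  # leave-one-out on a 20-sample toy via the unstratified mode
  toy <- separable_fixture(n = 10, seed = 4)
  cv <- cross_validate(toy, k = 20, seed = 1, stratify = FALSE)
  expect_identical(cv$folds, 20L)
  expect_true(all(vapply(cv$per_fold, function(cm)
    cm$tp + cm$fp + cm$fn + cm$tn, integer(1)) == 1L))
  expect_identical(cv$pooled$accuracy, 1)
})

test_that("label-shuffled data cross-validate near chance", {
  accs <- numeric(10)
  for (s in 1:10) {
    nl <- null_fixture(n = 30, p = 3, seed = 500 + s)
    accs[s] <- cross_validate(nl, k = 5, seed = s)$mean$accuracy
  }
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("mean-of-folds equals pooled accuracy for equal fold sizes", {
  set.seed(6)
  lm <- labeled_matrix(matrix(rnorm(200), 100, 2),
                       rep(c("A", "B"), c(60, 40)))
  cv <- cross_validate(lm, k = 10, seed = 4)
  expect_equal(cv$mean$accuracy, cv$pooled$accuracy)
})
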