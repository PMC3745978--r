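#' Within-class clustering cost
#'
#' The supervised clustering objective minimized by the bee colony for one
#' class: the mean plain Euclidean distance between a candidate class
#' center and the class's training samples,
#' `f = (1 / D_Train) * sum_j d(x_j, center)`. Division by the number of
#' training samples normalizes the cost so it does not scale with the
#' sample count.
#'
#' @param center numeric center vector.
#' @param samples numeric matrix of class samples (rows), same dimension.
#' @return Nonnegative scalar cost.
#' @examples
#' within_class_cost(1, matrix(c(0, 4), 2, 1)) # (1 + 3) / 2 = 2
#' @export
within_class_cost <- function(center, samples) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (!is.matrix(samples) || nrow(samples) == 0L) {
    stop("samples must be a nonempty matrix")
  }
  center <- as.double(center)
  if (length(center) != ncol(samples)) {
    stop("center dimension must match the sample dimension")
  }
  sum(sqrt(colSums((t(samples) - center)^2))) / nrow(samples)
}

# internal pure-R reference for the compiled kernel's cost: accumulates in
# plain doubles in the same row-then-dimension order as src/abc.cpp so the
# two training backends produce bit-identical trajectories
center_cost_r <- function(center, samples) {
  total <- 0
  for (r in seq_len(nrow(samples))) {
    s <- 0
    for (j in seq_along(center)) {
      diff <- samples[r, j] - center[j]
      s <- s + diff * diff
    }
    total <- total + sqrt(s)
  }
  total / nrow(samples)
}

#' Hard-assignment k-means objective
#'
#' Diagnostic sum-of-squares objective
#' `J(w, z) = sum_i sum_j w_ij ||x_i - z_j||^2` over a 0/1 assignment
#' matrix whose rows sum to one. Not on the training path; provided as an
#' oracle for the squared-distance clustering criterion.
#'
#' @param assignments `N x K` 0/1 matrix, one 1 per row.
#' @param features `N x d` sample matrix.
#' @param centers `K x d` matrix of cluster centers.
#' @return Nonnegative scalar.
#' @export
kmeans_objective <- function(assignments, features, centers) {
  assignments <- as.matrix(assignments)
  features <- as.matrix(features)
  centers <- as.matrix(centers)
  if (nrow(assignments) != nrow(features) ||
      ncol(assignments) != nrow(centers) ||
      ncol(features) != ncol(centers)) {
    stop("dimension mismatch between assignments, features and centers")
  }
  if (!all(assignments %in% c(0, 1)) || any(rowSums(assignments) != 1)) {
    stop("each row of assignments must contain exactly one 1")
  }
  j <- max.col(assignments, ties.method = "first")
  sum(rowSums((features - centers[j, , drop = FALSE])^2))
}

#' Per-coordinate mean of a sample block
#'
#' The cluster-center formula for hard assignments: the arithmetic mean of
#' the samples in a cluster, which minimizes the squared-distance
#' objective. Used as an oracle reference for ABC-trained centers.
#'
#' @param samples nonempty numeric matrix, samples in rows.
#' @return Mean vector of length `ncol(samples)`.
#' @export
class_mean <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) == 0L) stop("samples must be nonempty")
  colMeans(samples)
}

#' Train per-class prototype centers with the bee colony
#'
#' For each class independently: the class's training samples are
#' restricted to the chosen feature subset, a box search space is built
#' from the per-dimension min/max of those samples, and [run_abc()] (or
#' its compiled equivalent) minimizes [within_class_cost()]. All `SN`
#' final food-source positions are kept as that class's prototype centers
#' (the food vectors "representing" the class), alongside the best-ever
#' position. Class `i` (in `class_set` order) is seeded with
#' `abc_config$seed + i`, keeping classes independent yet reproducible.
#'
#' @param train a [labeled_matrix()] with at least one sample per class.
#' @param subset feature column indices defining the subspace.
#' @param abc_config an [abc_config()]; `NULL` uses the defaults.
#' @param backend `"cpp"` (compiled, default) or `"r"` (pure R reference,
#'   much slower, intended for verification); both draw the same random
#'   stream in the same order and return bit-identical models.
#' @return A `class_center_model`: list with `centers_by_class` (named list
#'   of `SN x |subset|` matrices, rows are centers), `costs_by_class`,
#'   `best_by_class` (named list of `position`/`cost`), `feature_indices`,
#'   `class_set`.
#' @export
train_class_centers <- function(train, subset, abc_config = NULL,
                                backend = c("cpp", "r")) {
  if (is.null(abc_config)) abc_config <- default_abc_config()
  stopifnot(inherits(train, "labeled_matrix"),
            inherits(abc_config, "abc_config"))
  backend <- match.arg(backend)
  subset <- check_subset(train, subset)
  if (anyNA(train$features)) {
    stop("training features contain missing values; impute first")
  }
  centers <- costs <- best <- list()
  base_seed <- if (is.null(abc_config$seed)) 0L else abc_config$seed
  for (ci in seq_along(train$class_set)) {
    cls <- train$class_set[ci]
    x <- train$features[train$labels == cls, subset, drop = FALSE]
    if (nrow(x) == 0L) {
      stop(sprintf("cannot train centers: class '%s' has no training samples",
                   cls))
    }
    lo <- apply(x, 2L, min)
    hi <- apply(x, 2L, max)
    seed_c <- mix_seed(base_seed + ci)
    if (backend == "cpp") {
      set.seed(seed_c)
      res <- abc_cluster_cpp(x, lo, hi, abc_config$sn, abc_config$max_cycles,
                             abc_config$limit)
      centers[[cls]] <- res$positions
      costs[[cls]] <- res$costs
      best[[cls]] <- list(position = res$best_position, cost = res$best_cost)
    } else {
      cfg <- abc_config
      cfg$seed <- seed_c
      res <- run_abc(function(z) center_cost_r(z, x),
                     search_space(lo, hi), cfg)
      pos <- do.call(rbind, lapply(res$foods, function(f) f$position))
      centers[[cls]] <- pos
      costs[[cls]] <- vapply(res$foods, function(f) f$cost, numeric(1))
      best[[cls]] <- list(position = res$best_position, cost = res$best_cost)
    }
    colnames(centers[[cls]]) <- colnames(train$features)[subset]
  }
  structure(list(centers_by_class = centers, costs_by_class = costs,
                 best_by_class = best, feature_indices = subset,
                 class_set = train$class_set),
            class = "class_center_model")
}

#' @export
print.class_center_model <- function(x, ...) {
  cat(sprintf(
    "class_center_model: %d classes x %d centers in %d feature(s) [%s]\n",
    length(x$class_set), nrow(x$centers_by_class[[1L]]),
    length(x$feature_indices), paste(x$feature_indices, collapse = ", ")))
  invisible(x)
}

#' Nearest-food classification
#'
#' Assigns each query point the class of the single nearest trained center
#' (plain Euclidean distance) across all classes' center lists. Ties are
#' broken toward the class appearing first in `class_set`.
#'
#' @param model a `class_center_model` from [train_class_centers()].
#' @param x query vector, or matrix of query rows, already restricted to
#'   `model$feature_indices` (i.e. with `length(model$feature_indices)`
#'   columns).
#' @param centers `"all"` (default) classifies against every trained food
#'   vector; `"best"` uses only each class's best-cost center.
#' @return Character vector of predicted class labels.
#' @export
classify_nearest_food <- function(model, x, centers = c("all", "best")) {
  stopifnot(inherits(model, "class_center_model"))
  centers <- match.arg(centers)
  if (!is.matrix(x)) x <- matrix(as.double(x), nrow = 1L)
  d <- length(model$feature_indices)
  if (ncol(x) != d) {
    stop(sprintf("query has %d columns but the model lives in %d feature(s)",
                 ncol(x), d))
  }
  if (centers == "all") {
    cmat <- do.call(rbind, model$centers_by_class[model$class_set])
    cls_of <- rep(model$class_set,
                  vapply(model$centers_by_class[model$class_set], nrow,
                         integer(1)))
  } else {
    cmat <- do.call(rbind, lapply(model$best_by_class[model$class_set],
                                  function(b) b$position))
    cls_of <- model$class_set
  }
  # squared distances suffice for the argmin; ties resolve to the first
  # (earliest-class) center because centers are stacked in class_set order
  d2 <- outer(rowSums(x^2), rep(1, nrow(cmat))) -
    2 * x %*% t(cmat) + outer(rep(1, nrow(x)), rowSums(cmat^2))
  cls_of[apply(d2, 1L, which.min)]
}
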