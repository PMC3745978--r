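#' Deterministic seed mixing
#'
#' Derives a reproducible child seed from a base seed and any number of
#' integer tags (step, candidate, run, ...). Uses a linear-congruential
#' hash modulo 2^31 - 1 so that derived seeds for different tag tuples are
#' decorrelated and always fit in a 32-bit integer.
#'
#' @param ... integers (or doubles holding integers) to mix, in order.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @examples
#' mix_seed(42, 1, 3)
#' @export
mix_seed <- function(...) {
  vals <- c(...)
  if (length(vals) == 0L) stop("mix_seed() needs at least one value")
  m <- 2147483647
  h <- 0
  for (v in vals) {
    h <- (h * 69069 + (as.double(v) %% m)) %% m
  }
  as.integer(h)
}

#' Labeled feature matrix
#'
#' The package's basic data container: an `N x d` numeric feature matrix
#' together with a class label per row and an ordered set of class labels.
#' The ordering of `class_set` is semantic: it fixes tie-breaks in
#' nearest-prototype classification and the mapping of the two classes to
#' the -1/+1 sides of the SVM.
#'
#' @param features numeric matrix (or coercible data frame), samples in rows.
#' @param labels vector of class labels, one per row of `features`.
#' @param class_set ordered distinct labels; defaults to `sort(unique(labels))`.
#' @return An object of class `labeled_matrix`: a list with elements
#'   `features`, `labels` (character) and `class_set` (character).
#' @examples
#' lm <- labeled_matrix(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
#' @export
labeled_matrix <- function(features, labels, class_set = NULL) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("features must be a numeric matrix")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) {
    stop("labels must have one entry per row of features")
  }
  if (is.null(class_set)) class_set <- sort(unique(labels))
  class_set <- as.character(class_set)
  if (anyDuplicated(class_set)) stop("class_set must be distinct")
  if (!all(labels %in% class_set)) {
    stop("every label must belong to class_set")
  }
  structure(list(features = features, labels = labels, class_set = class_set),
            class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix: %d samples x %d features, classes: %s\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s (n=%d)", x$class_set,
                            tabulate(factor(x$labels, levels = x$class_set))),
                    collapse = ", ")))
  invisible(x)
}

#' Row subset of a labeled matrix
#'
#' @param data a [labeled_matrix()].
#' @param idx row indices to keep.
#' @return A `labeled_matrix` with the selected rows and the same `class_set`.
#' @export
subset_rows <- function(data, idx) {
  stopifnot(inherits(data, "labeled_matrix"))
  labeled_matrix(data$features[idx, , drop = FALSE], data$labels[idx],
                 class_set = data$class_set)
}

# internal: validate a feature-index subset against a labeled_matrix
check_subset <- function(data, subset) {
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("feature subset must be nonempty")
  if (anyDuplicated(subset)) stop("feature subset must not contain duplicates")
  if (any(subset < 1L) || any(subset > ncol(data$features))) {
    stop("feature subset indices out of range")
  }
  subset
}
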