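#' Linear SVM configuration
#'
#' Training parameters for the downstream classifier stage: linear kernel,
#' sequential-minimal-optimization training, KKT tolerance 1e-3, iteration
#' cap 15000, kernel cache 5000 (MB in the backing library), and cost
#' parameter `C = 1`.
#'
#' @param kernel only `"linear"` is supported.
#' @param kkt_tolerance SMO stopping tolerance on the KKT conditions.
#' @param max_iterations iteration cap recorded in the config (the backing
#'   SMO solver iterates to `kkt_tolerance`).
#' @param cache_limit kernel cache size.
#' @param cost_C positive soft-margin cost parameter.
#' @return An `svm_config` object.
#' @export
svm_config <- function(kernel = "linear", kkt_tolerance = 1e-3,
                       max_iterations = 15000L, cache_limit = 5000L,
                       cost_C = 1) {
  kernel <- match.arg(kernel, "linear")
  if (cost_C <= 0) stop("cost_C must be positive")
  if (kkt_tolerance <= 0) stop("kkt_tolerance must be positive")
  structure(list(kernel = kernel, kkt_tolerance = kkt_tolerance,
                 max_iterations = as.integer(max_iterations),
                 cache_limit = as.integer(cache_limit),
                 cost_C = cost_C),
            class = "svm_config")
}

default_svm_config <- function() svm_config()

#' Construct a linear decision rule directly
#'
#' Builds a `trained_svm` object from an explicit weight vector and bias,
#' bypassing training. Predictions are `class_set[2]` when
#' `w . x + b >= 0` and `class_set[1]` otherwise (points exactly on the
#' hyperplane go to the positive class).
#'
#' @param weight_vector numeric weight vector `w`.
#' @param bias scalar bias `b`.
#' @param class_set length-2 ordered labels; `class_set[1]` maps to the -1
#'   side, `class_set[2]` to the +1 side.
#' @param support_info optional list of training diagnostics.
#' @return A `trained_svm` object.
#' @export
trained_svm <- function(weight_vector, bias, class_set,
                        support_info = list()) {
  if (length(class_set) != 2L) stop("class_set must contain exactly 2 labels")
  structure(list(weight_vector = as.double(weight_vector),
                 bias = as.double(bias)[1L],
                 class_set = as.character(class_set),
                 support_info = support_info),
            class = "trained_svm")
}

#' Train a linear SVM
#'
#' Fits a soft-margin linear SVM by sequential minimal optimization
#' (delegated to the libsvm solver in \pkg{e1071}; no feature scaling is
#' applied here) and extracts the primal hyperplane `(w, b)` oriented so
#' that `class_set[2]` is the positive (+1) side. At convergence the dual
#' coefficients satisfy `sum_i y_i alpha_i = 0` and `0 <= alpha_i <= C`
#' within the KKT tolerance; they are kept in `support_info`.
#'
#' @param train a [labeled_matrix()] with exactly 2 classes and no missing
#'   values.
#' @param config an [svm_config()].
#' @return A [trained_svm()] with `support_info` carrying the number of
#'   support vectors, the dual coefficients `y_i alpha_i`, and the fitted
#'   backing model.
#' @export
train_svm <- function(train, config = svm_config()) {
  stopifnot(inherits(train, "labeled_matrix"),
            inherits(config, "svm_config"))
  if (length(train$class_set) != 2L) {
    stop("the SVM stage supports exactly 2 classes")
  }
  if (anyNA(train$features)) stop("training features contain missing values")
  if (!all(train$class_set %in% train$labels)) {
    stop("both classes must be present in the training data")
  }
  y <- factor(train$labels, levels = train$class_set)
  fit <- e1071::svm(x = train$features, y = y, type = "C-classification",
                    kernel = "linear", cost = config$cost_C,
                    tolerance = config$kkt_tolerance,
                    cachesize = config$cache_limit, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision value toward the first label it encounters;
  # flip so that positive values always mean class_set[2]
  pos_level <- fit$levels[fit$labels[1L]]
  if (!identical(pos_level, train$class_set[2L])) {
    w <- -w
    b <- -b
  }
  trained_svm(w, b, train$class_set,
              support_info = list(n_support = nrow(fit$SV),
                                  dual_coefs = as.double(fit$coefs),
                                  cost_C = config$cost_C,
                                  fit = fit))
}

#' Predict classes from a linear SVM
#'
#' Applies the sign rule: `class_set[2]` where `w . x + b >= 0`, else
#' `class_set[1]`.
#'
#' @param object a [trained_svm()].
#' @param x query vector or matrix of query rows with `length(w)` columns.
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.trained_svm <- function(object, x, ...) {
  if (!is.matrix(x)) x <- matrix(as.double(x), nrow = 1L)
  if (ncol(x) != length(object$weight_vector)) {
    stop(sprintf("query has %d columns but the model was trained on %d",
                 ncol(x), length(object$weight_vector)))
  }
  dv <- drop(x %*% object$weight_vector) + object$bias
  object$class_set[ifelse(dv >= 0, 2L, 1L)]
}

#' @export
print.trained_svm <- function(x, ...) {
  cat(sprintf("trained_svm: linear, %d feature(s), classes %s (-1) / %s (+1)\n",
              length(x$weight_vector), x$class_set[1L], x$class_set[2L]))
  invisible(x)
}
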