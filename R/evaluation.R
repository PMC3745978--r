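#' Binary confusion matrix
#'
#' Counts true/false positives/negatives for a designated positive class.
#'
#' @param y_true,y_pred equal-length label vectors drawn from a binary
#'   class set.
#' @param positive_class the label counted as positive.
#' @param class_set optional length-2 label universe for validation;
#'   defaults to the distinct labels observed.
#' @return A `confusion_matrix`: list with integer `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion(c("d", "d", "l"), c("d", "l", "l"), positive_class = "d")
#' @export
confusion <- function(y_true, y_pred, positive_class, class_set = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (length(y_true) == 0L) stop("label vectors must be nonempty")
  if (is.null(class_set)) class_set <- unique(c(y_true, y_pred))
  class_set <- as.character(class_set)
  if (length(class_set) > 2L) {
    stop("confusion() is defined for binary class sets only")
  }
  if (!all(c(y_true, y_pred) %in% class_set)) {
    stop("unknown label outside the class set")
  }
  if (!positive_class %in% class_set) {
    stop(sprintf("positive class '%s' is not in the class set",
                 positive_class))
  }
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 positive_class = positive_class),
            class = "confusion_matrix")
}

#' Performance metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+FP+FN+TN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)` and negative
#' predictive value `TN/(TN+FN)`, as proportions in `[0, 1]`. A metric
#' whose denominator is zero is reported as `NA` and listed in
#' `undefined`, never silently as 0.
#'
#' @param cm a [confusion()] matrix with at least one counted sample.
#' @return A `classifier_metrics` list: `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, plus `undefined` (character vector of
#'   metric names with zero denominators).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0L) stop("confusion matrix counts no samples")
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  out <- list(accuracy = (cm$tp + cm$tn) / total,
              sensitivity = ratio(cm$tp, cm$tp + cm$fn),
              specificity = ratio(cm$tn, cm$tn + cm$fp),
              ppv = ratio(cm$tp, cm$tp + cm$fp),
              npv = ratio(cm$tn, cm$tn + cm$fn))
  out$undefined <- names(out)[vapply(out, function(v) is.na(v), logical(1))]
  structure(out, class = "classifier_metrics")
}

#' Stratified k-fold partition
#'
#' Shuffles each class independently and deals its samples round-robin
#' into `k` folds, so every sample sits in exactly one validation fold and
#' per-fold class proportions match the data within one sample.
#'
#' @param data a [labeled_matrix()] or a label vector; when stratifying,
#'   every class needs at least `k` samples.
#' @param k number of folds.
#' @param seed optional integer seed.
#' @param stratify deal each class separately (default). With
#'   `stratify = FALSE` all samples are dealt jointly, which permits
#'   leave-one-out (`k` = sample count) and classes smaller than `k`.
#' @return List of `k` elements, each a list with integer `train` and
#'   `validation` index vectors.
#' @export
stratified_kfold <- function(data, k, seed = NULL, stratify = TRUE) {
  labels <- if (inherits(data, "labeled_matrix")) data$labels
            else as.character(data)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > length(labels)) stop("k cannot exceed the sample count")
  if (!is.null(seed)) set.seed(seed)
  fold_of <- integer(length(labels))
  groups <- if (stratify) unique(labels) else "all"
  for (cls in groups) {
    idx <- if (stratify) which(labels == cls) else seq_along(labels)
    if (stratify && length(idx) < k) {
      stop(sprintf("class '%s' has %d samples, fewer than k = %d folds",
                   cls, length(idx), k))
    }
    fold_of[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), validation = which(fold_of == f))
  })
}

#' Cross-validated SVM evaluation
#'
#' Stratified k-fold cross-validation of the linear SVM on a feature
#' subset: per fold, the SVM is trained on the restricted training
#' columns and evaluated on the held-out fold. Reports the mean of the
#' per-fold metrics (the conventional k-fold summary) alongside metrics of
#' the pooled confusion counts.
#'
#' @param data a [labeled_matrix()] with 2 classes and no missing values.
#' @param subset feature column indices (default: all features).
#' @param k number of folds (default 10).
#' @param svm_config an [svm_config()]; `NULL` uses the defaults.
#' @param seed integer seed for the fold partition.
#' @param positive_class label counted as positive; defaults to the
#'   second entry of `class_set` (the +1-mapped class).
#' @param stratify passed to [stratified_kfold()]; `FALSE` permits
#'   leave-one-out and classes smaller than `k`.
#' @return A `cv_report`: list with `folds`, `per_fold` (confusion
#'   matrices), `per_fold_metrics`, `mean` (mean-of-folds metrics, `NA`
#'   folds dropped per metric), `pooled` (metrics of summed counts),
#'   `positive_class`, `subset`.
#' @export
cross_validate <- function(data, subset = seq_len(ncol(data$features)),
                           k = 10L, svm_config = NULL, seed = 1L,
                           positive_class = data$class_set[2L],
                           stratify = TRUE) {
  if (is.null(svm_config)) svm_config <- default_svm_config()
  stopifnot(inherits(data, "labeled_matrix"))
  subset <- check_subset(data, subset)
  folds <- stratified_kfold(data, k, seed = seed, stratify = stratify)
  per_fold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- subset_rows(data, folds[[f]]$train)
    va <- subset_rows(data, folds[[f]]$validation)
    tr$features <- tr$features[, subset, drop = FALSE]
    model <- train_svm(tr, svm_config)
    pred <- predict(model, va$features[, subset, drop = FALSE])
    per_fold[[f]] <- confusion(va$labels, pred, positive_class,
                               class_set = data$class_set)
  }
  per_fold_metrics <- lapply(per_fold, metrics)
  metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  mean_metrics <- lapply(metric_names, function(m) {
    vals <- vapply(per_fold_metrics, `[[`, numeric(1), m)
    mean(vals, na.rm = TRUE)
  })
  names(mean_metrics) <- metric_names
  pooled_cm <- structure(list(
    tp = sum(vapply(per_fold, `[[`, integer(1), "tp")),
    fp = sum(vapply(per_fold, `[[`, integer(1), "fp")),
    fn = sum(vapply(per_fold, `[[`, integer(1), "fn")),
    tn = sum(vapply(per_fold, `[[`, integer(1), "tn")),
    positive_class = positive_class), class = "confusion_matrix")
  structure(list(folds = length(folds), per_fold = per_fold,
                 per_fold_metrics = per_fold_metrics,
                 mean = mean_metrics, pooled = metrics(pooled_cm),
                 positive_class = positive_class, subset = subset),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold, positive class '%s', features [%s]\n",
              x$folds, x$positive_class, paste(x$subset, collapse = ", ")))
  cat(sprintf(
    "  mean of folds: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, PPV %.2f%%, NPV %.2f%%\n",
    100 * x$mean$accuracy, 100 * x$mean$sensitivity,
    100 * x$mean$specificity, 100 * x$mean$ppv, 100 * x$mean$npv))
  invisible(x)
}
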