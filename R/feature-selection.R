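#' Stratified train/test split
#'
#' Per class, `floor(train_fraction * n_class)` samples go to the training
#' part (sampled without replacement) and the remainder to the test part,
#' so per-class proportions are preserved within one sample. The default
#' fraction is the 75/25 scoring split used by the wrapper.
#'
#' @param data a [labeled_matrix()] with at least 2 samples per class.
#' @param train_fraction in (0, 1); default 0.75.
#' @param seed optional integer seed (uses the current stream when `NULL`).
#' @return List with `train` and `test` labeled matrices partitioning the
#'   input.
#' @export
stratified_split <- function(data, train_fraction = 0.75, seed = NULL) {
  stopifnot(inherits(data, "labeled_matrix"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  if (!is.null(seed)) set.seed(seed)
  train_idx <- integer(0)
  for (cls in data$class_set) {
    idx <- which(data$labels == cls)
    if (length(idx) < 2L) {
      stop(sprintf("class '%s' has fewer than 2 samples; cannot split", cls))
    }
    n_tr <- floor(train_fraction * length(idx))
    if (n_tr < 1L || n_tr >= length(idx)) {
      stop(sprintf(
        "class '%s' would get an empty train or test part at fraction %g",
        cls, train_fraction))
    }
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  test_idx <- setdiff(seq_along(data$labels), train_idx)
  list(train = subset_rows(data, sort(train_idx)),
       test = subset_rows(data, test_idx))
}

#' Score a feature subset by ABC-clustering classification
#'
#' The wrapper's objective function: `runs` times, draw a stratified 75/25
#' split, train per-class prototype centers on the training part with
#' [train_class_centers()], classify the held-out part with
#' [classify_nearest_food()], and record the accuracy. Reports the mean
#' and standard deviation across runs. Each run uses seeds derived from
#' `abc_config$seed` via [mix_seed()], so candidates scored with different
#' base seeds see decorrelated splits.
#'
#' @param data a [labeled_matrix()] without missing values.
#' @param subset nonempty feature column indices.
#' @param runs positive integer; 100 replicates by default.
#' @param abc_config an [abc_config()] (`NULL` = defaults); its `seed`
#'   is the base seed.
#' @param train_fraction scoring split fraction, default 0.75.
#' @param fixed_split reuse the run-1 split in every run (default `FALSE`,
#'   i.e. a fresh split per run).
#' @return List with `mean_accuracy`, `std` (0 when `runs == 1`) and the
#'   per-run `accuracies`.
#' @export
score_subset <- function(data, subset, runs = 100L,
                         abc_config = NULL, train_fraction = 0.75,
                         fixed_split = FALSE) {
  if (is.null(abc_config)) abc_config <- default_abc_config()
  stopifnot(inherits(data, "labeled_matrix"))
  subset <- check_subset(data, subset)
  runs <- as.integer(runs)
  if (runs < 1L) stop("runs must be a positive integer")
  base <- if (is.null(abc_config$seed)) 0L else abc_config$seed
  # the split depends only on the labels, so restrict the columns once
  work <- labeled_matrix(data$features[, subset, drop = FALSE], data$labels,
                         class_set = data$class_set)
  accs <- numeric(runs)
  for (r in seq_len(runs)) {
    split_tag <- if (fixed_split) 1L else r
    sp <- stratified_split(work, train_fraction,
                           seed = mix_seed(base, split_tag, 11L))
    cfg <- abc_config
    cfg$seed <- mix_seed(base, r, 17L)
    model <- train_class_centers(sp$train, seq_along(subset), cfg)
    pred <- classify_nearest_food(model, sp$test$features)
    accs[r] <- mean(pred == sp$test$labels)
  }
  list(mean_accuracy = mean(accs),
       std = if (runs > 1L) stats::sd(accs) else 0,
       accuracies = accs)
}

#' Sequential forward selection scored by ABC clustering (ABCFS)
#'
#' Starting from the empty set, each step scores every unselected feature
#' appended to the current subset with [score_subset()] and adds the
#' argmax (ties broken toward the lowest feature index). The search
#' repeats while the performance trend is rising: selection stops as soon
#' as the step-best mean score fails to improve on the previous step's
#' score by more than `min_improvement` (the non-improving feature is not
#' included), when `max_features` is reached, or when all features are
#' used.
#'
#' @param data a [labeled_matrix()] without missing values.
#' @param max_features cap on the subset size; defaults to all features.
#' @param runs scoring replicates per candidate subset (default 100).
#' @param abc_config an [abc_config()]; its `seed` is the base seed for
#'   the whole selection (step/candidate/run seeds are derived with
#'   [mix_seed()]).
#' @param min_improvement continue only while the step-best score exceeds
#'   the previous score by more than this margin; default 0 (any step that
#'   does not strictly improve ends the search).
#' @param scorer optional deterministic scorer `function(data, subset)`
#'   returning a single numeric score, replacing the ABC-clustering
#'   objective (used for oracle comparisons).
#' @param train_fraction,fixed_split passed to [score_subset()].
#' @return An `abcfs_selection`: list with `selected_features` (ordered),
#'   `steps` (per accepted/declined step: `subset`, named
#'   `candidate_scores`, `chosen_feature`, `mean_score`, `score_std`),
#'   `stop_reason` (one of `"score_declined"`, `"max_features_reached"`,
#'   `"all_features_used"`) and `runs_per_evaluation`.
#' @export
abcfs_select <- function(data, max_features = ncol(data$features),
                         runs = 100L, abc_config = NULL,
                         min_improvement = 0, scorer = NULL,
                         train_fraction = 0.75, fixed_split = FALSE) {
  if (is.null(abc_config)) abc_config <- default_abc_config()
  stopifnot(inherits(data, "labeled_matrix"))
  p <- ncol(data$features)
  max_features <- as.integer(max_features)
  if (max_features < 1L || max_features > p) {
    stop("max_features must be between 1 and the feature count")
  }
  base <- if (is.null(abc_config$seed)) 0L else abc_config$seed
  selected <- integer(0)
  steps <- list()
  prev_score <- -Inf
  stop_reason <- "all_features_used"
  step <- 0L
  while (length(selected) < max_features) {
    step <- step + 1L
    candidates <- setdiff(seq_len(p), selected)
    scores <- stds <- numeric(length(candidates))
    for (ci in seq_along(candidates)) {
      f <- candidates[ci]
      if (is.null(scorer)) {
        # common random numbers: all candidates at a step share one
        # resampling design (splits + training seeds), so they are
        # compared paired; each step draws a fresh design to avoid
        # compounding adaptation to a single set of splits
        cfg <- abc_config
        cfg$seed <- mix_seed(base, step)
        sc <- score_subset(data, c(selected, f), runs = runs,
                           abc_config = cfg, train_fraction = train_fraction,
                           fixed_split = fixed_split)
        scores[ci] <- sc$mean_accuracy
        stds[ci] <- sc$std
      } else {
        scores[ci] <- scorer(data, c(selected, f))
        stds[ci] <- 0
      }
    }
    # exact score ties between stochastic evaluations are resolved by
    # paired runoff replicates on fresh designs; a deterministic scorer
    # reproduces its values, so ties then fall to the lowest feature
    # index as the final deterministic rule
    tied <- which(scores == max(scores))
    for (round in 1:2) {
      if (length(tied) < 2L) break
      runoff <- vapply(tied, function(ci) {
        f <- candidates[ci]
        if (is.null(scorer)) {
          cfg <- abc_config
          cfg$seed <- mix_seed(base, step, 90L + round)
          score_subset(data, c(selected, f), runs = runs, abc_config = cfg,
                       train_fraction = train_fraction,
                       fixed_split = fixed_split)$mean_accuracy
        } else {
          scorer(data, c(selected, f))
        }
      }, numeric(1))
      tied <- tied[runoff == max(runoff)]
    }
    best_ci <- tied[1L]  # candidates ascend, so residual ties -> lowest index
    best_f <- candidates[best_ci]
    rec <- list(subset = selected, chosen_feature = best_f,
                candidate_scores = stats::setNames(scores,
                                                   as.character(candidates)),
                mean_score = scores[best_ci], score_std = stds[best_ci])
    if (scores[best_ci] <= prev_score + min_improvement) {
      rec$accepted <- FALSE
      steps[[step]] <- rec
      stop_reason <- "score_declined"
      break
    }
    rec$accepted <- TRUE
    steps[[step]] <- rec
    selected <- c(selected, best_f)
    prev_score <- scores[best_ci]
    if (length(selected) == p) {
      stop_reason <- "all_features_used"
      break
    }
    if (length(selected) == max_features) {
      stop_reason <- "max_features_reached"
      break
    }
  }
  structure(list(selected_features = selected, steps = steps,
                 stop_reason = stop_reason,
                 runs_per_evaluation = as.integer(runs)),
            class = "abcfs_selection")
}

#' @export
print.abcfs_selection <- function(x, ...) {
  cat(sprintf("abcfs_selection: %d feature(s) [%s], stopped: %s\n",
              length(x$selected_features),
              paste(x$selected_features, collapse = ", "), x$stop_reason))
  for (s in x$steps) {
    cat(sprintf("  step %d: %s feature %d, mean score %.4f (sd %.4f)\n",
                length(s$subset) + 1L,
                if (isTRUE(s$accepted)) "added" else "declined",
                s$chosen_feature, s$mean_score, s$score_std))
  }
  invisible(x)
}

#' Selection trace as a data frame
#'
#' @param x an `abcfs_selection`.
#' @param ... unused.
#' @return Data frame with one row per step: `step`, `chosen_feature`,
#'   `accepted`, `mean_score`, `score_std`.
#' @export
as.data.frame.abcfs_selection <- function(x, ...) {
  data.frame(step = seq_along(x$steps),
             chosen_feature = vapply(x$steps, `[[`, integer(1),
                                     "chosen_feature"),
             accepted = vapply(x$steps, function(s) isTRUE(s$accepted),
                               logical(1)),
             mean_score = vapply(x$steps, `[[`, numeric(1), "mean_score"),
             score_std = vapply(x$steps, `[[`, numeric(1), "score_std"))
}
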