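#' Assemble a full pipeline configuration
#'
#' Collects every stage's settings in one serializable list: input
#' location (a delimited file or a synthetic [synth_spec()]), preparation
#' switches, selection settings, bee-colony parameters, SVM parameters,
#' cross-validation settings and the global seed. The object round-trips
#' losslessly through JSON via [write_run_config()] / [read_run_config()].
#'
#' @param input path to a delimited dataset, or `NULL` when `synthetic`
#'   is given.
#' @param label_column class column name (file input without schema).
#' @param schema packaged schema name or schema file path, or `NULL`.
#' @param synthetic a [synth_spec()] (or plain list of its fields), or
#'   `NULL` for file input.
#' @param impute `"mode"`, `"mean"` or `"none"`.
#' @param scale min-max scale the features; defaults to `TRUE` for file
#'   input and `FALSE` for synthetic data (generated on a common scale).
#' @param max_features cap on the selected subset size; `NULL` for all.
#' @param runs scoring replicates per candidate subset.
#' @param min_improvement selection stopping epsilon (see
#'   [abcfs_select()]).
#' @param colony_size,max_cycles,limit bee-colony parameters
#'   (see [abc_config()]).
#' @param folds cross-validation folds.
#' @param positive_class label counted as positive; `NULL` for the second
#'   class.
#' @param cost_C,kkt_tolerance SVM parameters (see [svm_config()]).
#' @param seed global seed; every stage seed is derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, label_column = "class", schema = NULL,
                       synthetic = NULL, impute = "mode", scale = NULL,
                       max_features = NULL, runs = 100L,
                       min_improvement = 0, colony_size = 20L,
                       max_cycles = 300L, limit = 200L, folds = 10L,
                       positive_class = NULL, cost_C = 1,
                       kkt_tolerance = 1e-3, seed = 1L) {
  if (is.null(input) && is.null(synthetic)) {
    stop("give either an input file or a synthetic spec")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synth_spec")) {
    synthetic <- do.call(synth_spec, synthetic)
  }
  if (is.null(scale)) scale <- is.null(synthetic)
  structure(list(input = input, label_column = label_column,
                 schema = schema, synthetic = synthetic, impute = impute,
                 scale = isTRUE(scale),
                 max_features = if (!is.null(max_features))
                   as.integer(max_features),
                 runs = as.integer(runs),
                 min_improvement = as.double(min_improvement),
                 colony_size = as.integer(colony_size),
                 max_cycles = as.integer(max_cycles),
                 limit = as.integer(limit), folds = as.integer(folds),
                 positive_class = positive_class,
                 cost_C = as.double(cost_C),
                 kkt_tolerance = as.double(kkt_tolerance),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [run_config()].
#' @param path JSON file.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (!is.null(x$synthetic)) x$synthetic <- unclass(x$synthetic)
  x <- x[!vapply(x, is.null, logical(1))]  # absent fields use defaults
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(x$synthetic)) x$synthetic <- do.call(synth_spec, x$synthetic)
  do.call(run_config, x)
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
}

#' Run the two-phase pipeline
#'
#' Executes the full system: load or generate the data, impute missing
#' cells, optionally min-max scale, run ABCFS feature selection (phase 1),
#' then evaluate a linear SVM on the selected features with stratified
#' k-fold cross-validation (phase 2). Writes `selection_trace.json`,
#' `report.json`, `run_log.json` (every parameter and derived seed) and a
#' `MANIFEST.json` marking completeness to `out_dir`. Outputs contain no
#' timestamps, so identical configurations produce byte-identical
#' artifacts.
#'
#' @param config a [run_config()] or the path to its JSON file.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with `selection` (an `abcfs_selection`),
#'   `report` (a `cv_report`) and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(trace = file.path(out_dir, "selection_trace.json"),
                report = file.path(out_dir, "report.json"),
                log = file.path(out_dir, "run_log.json"),
                manifest = file.path(out_dir, "MANIFEST.json"))
  manifest <- list(artifacts = list(), complete = FALSE)
  flush_manifest <- function() write_report_json(manifest, paths$manifest)
  on.exit(flush_manifest())

  # phase 0: data
  if (!is.null(config$synthetic)) {
    gen <- generate_dataset(config$synthetic)
    data <- gen$data
    mask <- gen$mask
  } else {
    rd <- read_dataset(config$input, label_column = config$label_column,
                       schema = config$schema)
    data <- rd$data
    mask <- rd$mask
  }
  if (any(mask) && config$impute != "none") {
    data <- impute_mode_per_class(data, mask, method = config$impute)
  }
  if (anyNA(data$features)) {
    stop("data still contain missing values; set impute to 'mode' or 'mean'")
  }
  if (config$scale) data <- minmax_scale(data)$data

  abc_cfg <- abc_config(colony_size = config$colony_size,
                        max_cycles = config$max_cycles,
                        limit = config$limit,
                        seed = mix_seed(config$seed, 1L))
  max_f <- config$max_features %||% ncol(data$features)

  # phase 1: ABCFS feature selection
  selection <- abcfs_select(data, max_features = max_f, runs = config$runs,
                            abc_config = abc_cfg,
                            min_improvement = config$min_improvement)
  trace <- list(selected_features = selection$selected_features,
                stop_reason = selection$stop_reason,
                runs_per_evaluation = selection$runs_per_evaluation,
                steps = lapply(selection$steps, function(s) {
                  list(subset = s$subset, chosen_feature = s$chosen_feature,
                       accepted = isTRUE(s$accepted),
                       mean_score = s$mean_score, score_std = s$score_std,
                       candidate_scores = as.list(s$candidate_scores))
                }))
  write_report_json(trace, paths$trace)
  manifest$artifacts$selection_trace <- "selection_trace.json"
  flush_manifest()

  # phase 2: SVM + k-fold cross-validation on the reduced data
  pos <- config$positive_class %||% data$class_set[2L]
  svm_cfg <- svm_config(cost_C = config$cost_C,
                        kkt_tolerance = config$kkt_tolerance)
  report <- cross_validate(data, subset = selection$selected_features,
                           k = config$folds, svm_config = svm_cfg,
                           seed = mix_seed(config$seed, 2L),
                           positive_class = pos)
  report_json <- list(
    folds = report$folds, positive_class = report$positive_class,
    selected_features = selection$selected_features,
    per_fold = lapply(report$per_fold, function(cm) {
      list(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
    }),
    mean = report$mean,
    pooled = unclass(report$pooled)[c("accuracy", "sensitivity",
                                      "specificity", "ppv", "npv")])
  write_report_json(report_json, paths$report)
  manifest$artifacts$report <- "report.json"

  log <- list(config = unclass(write_safe_config(config)),
              derived_seeds = list(selection_base = abc_cfg$seed,
                                   cv = mix_seed(config$seed, 2L)),
              n_samples = nrow(data$features),
              n_features = ncol(data$features),
              class_set = data$class_set)
  write_report_json(log, paths$log)
  manifest$artifacts$run_log <- "run_log.json"
  manifest$complete <- TRUE
  flush_manifest()
  invisible(list(selection = selection, report = report, paths = paths))
}

# internal: config as plain serializable list
write_safe_config <- function(config) {
  x <- unclass(config)
  if (!is.null(x$synthetic)) x$synthetic <- unclass(x$synthetic)
  x
}
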