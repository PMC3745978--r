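#' Load a packaged or user dataset schema
#'
#' Schemas describe the columns of a delimited dataset in file order: each
#' column has a `name`, a `kind` (`"continuous"`, `"binary"`, `"discrete"`
#' or `"label"`), optionally `levels` (the two raw tokens mapped to 0/1
#' for binary columns) and a documented `range` (`[min, max]`) used for
#' plausibility warnings. The package ships schemas for the three classic
#' UCI liver/diabetes benchmarks: `"hepatitis"`, `"liver_disorders"`,
#' `"diabetes"`.
#'
#' @param name packaged schema name or a path to a schema JSON file.
#' @return A `dataset_schema`: list with `name`, `columns`,
#'   `label_column`, `positive_class`, `header`, `separator`.
#' @export
load_schema <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "schemas", paste0(name, ".json"),
                package = "abcfs")
  if (!nzchar(path) || !file.exists(path)) {
    stop(sprintf("unknown schema '%s'", name))
  }
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cols <- lapply(js$columns, function(co) {
    list(name = co$name, kind = co$kind,
         levels = if (!is.null(co$levels)) as.character(unlist(co$levels)),
         range = if (!is.null(co$range)) as.double(unlist(co$range)))
  })
  kinds <- vapply(cols, `[[`, character(1), "kind")
  if (sum(kinds == "label") != 1L) {
    stop("schema must declare exactly one label column")
  }
  structure(list(name = js$name, columns = cols,
                 label_column = cols[[which(kinds == "label")]]$name,
                 positive_class = js$positive_class,
                 header = isTRUE(js$header),
                 separator = if (is.null(js$separator)) "," else js$separator),
            class = "dataset_schema")
}

#' Read a delimited classification dataset
#'
#' Parses a CSV/TSV (or header-less UCI `.data`) file into a
#' [labeled_matrix()] plus a missing-value mask. Cells equal to
#' `missing_marker` (UCI's `"?"` by default) become `NA` and are flagged
#' in the mask. With a schema, binary columns are mapped to 0/1 by their
#' declared level order and values outside a column's documented range
#' raise a warning (the value is kept). Without a schema, every non-label
#' column is parsed as numeric.
#'
#' @param path input file.
#' @param label_column name of the class column (required when no schema
#'   is given; a schema supplies its own).
#' @param schema optional [load_schema()] result or schema name.
#' @param missing_marker token marking missing cells.
#' @param header does the file carry a header row? Defaults to the schema
#'   declaration, else `TRUE`.
#' @param sep field separator; defaults to the schema declaration else ",".
#' @return List with `data` (a `labeled_matrix`, missing cells `NA`) and
#'   `mask` (logical matrix, `TRUE` where missing).
#' @export
read_dataset <- function(path, label_column = NULL, schema = NULL,
                         missing_marker = "?", header = NULL, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  if (is.character(schema)) schema <- load_schema(schema)
  if (is.null(header)) header <- if (is.null(schema)) TRUE else schema$header
  if (is.null(sep)) sep <- if (is.null(schema)) "," else schema$separator
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", strip.white = TRUE,
                           na.strings = character(0), quote = "\"",
                           comment.char = "")
  if (!is.null(schema)) {
    if (ncol(raw) != length(schema$columns)) {
      stop(sprintf("file has %d columns but schema '%s' declares %d",
                   ncol(raw), schema$name, length(schema$columns)))
    }
    names(raw) <- vapply(schema$columns, `[[`, character(1), "name")
    label_column <- schema$label_column
  }
  if (is.null(label_column) || !label_column %in% names(raw)) {
    stop("label column not found; give label_column= or a schema")
  }
  labels <- raw[[label_column]]
  if (any(labels == missing_marker | labels == "")) {
    stop("missing values in the label column are not allowed")
  }
  feat_names <- setdiff(names(raw), label_column)
  n <- nrow(raw)
  features <- matrix(NA_real_, n, length(feat_names),
                     dimnames = list(NULL, feat_names))
  mask <- matrix(FALSE, n, length(feat_names),
                 dimnames = list(NULL, feat_names))
  col_spec <- function(nm) {
    if (is.null(schema)) return(NULL)
    schema$columns[[which(vapply(schema$columns, `[[`, character(1),
                                 "name") == nm)]]
  }
  for (ci in seq_along(feat_names)) {
    nm <- feat_names[ci]
    tok <- raw[[nm]]
    miss <- tok == missing_marker
    mask[, ci] <- miss
    sp <- col_spec(nm)
    if (!is.null(sp) && identical(sp$kind, "binary") &&
        !is.null(sp$levels)) {
      val <- rep(NA_real_, n)
      val[tok == sp$levels[1L]] <- 0
      val[tok == sp$levels[2L]] <- 1
      bad <- which(!miss & is.na(val))
      if (length(bad)) {
        stop(sprintf("row %d: value '%s' in binary column '%s' not in {%s}",
                     bad[1L], tok[bad[1L]], nm,
                     paste(sp$levels, collapse = ", ")))
      }
    } else {
      val <- suppressWarnings(as.numeric(tok))
      bad <- which(!miss & is.na(val))
      if (length(bad)) {
        stop(sprintf("row %d: cannot parse value '%s' in column '%s'",
                     bad[1L], tok[bad[1L]], nm))
      }
      val[miss] <- NA_real_
    }
    if (!is.null(sp) && !is.null(sp$range)) {
      out_of <- which(!miss & (val < sp$range[1L] | val > sp$range[2L]))
      if (length(out_of)) {
        warning(sprintf(
          "column '%s': %d value(s) outside the documented range [%g, %g] (kept)",
          nm, length(out_of), sp$range[1L], sp$range[2L]))
      }
    }
    features[, ci] <- val
  }
  list(data = labeled_matrix(features, labels), mask = mask)
}

#' Impute missing cells by the within-class mode
#'
#' Each missing cell is replaced by the most frequently encountered
#' observed value of that feature within the sample's own class; ties go
#' to the smaller value. `method = "mean"` replaces the mode with the
#' within-class mean of observed values.
#'
#' @param data a [labeled_matrix()] whose missing cells are `NA`.
#' @param mask optional logical matrix flagging missing cells (defaults to
#'   `is.na(data$features)`). Observed cells are never altered.
#' @param method `"mode"` (default) or `"mean"`.
#' @return The completed `labeled_matrix`.
#' @export
impute_mode_per_class <- function(data, mask = NULL,
                                  method = c("mode", "mean")) {
  stopifnot(inherits(data, "labeled_matrix"))
  method <- match.arg(method)
  x <- data$features
  if (is.null(mask)) mask <- is.na(x)
  if (!identical(dim(mask), dim(x))) stop("mask dimensions must match")
  for (cls in data$class_set) {
    rows <- which(data$labels == cls)
    for (ci in seq_len(ncol(x))) {
      hole <- rows[mask[rows, ci]]
      if (length(hole) == 0L) next
      obs <- x[rows[!mask[rows, ci]], ci]
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0L) {
        stop(sprintf(
          "cannot impute: class '%s', feature '%s' has no observed values",
          cls, colnames(x)[ci] %||% as.character(ci)))
      }
      fill <- if (method == "mean") {
        mean(obs)
      } else {
        tab <- table(obs)
        min(as.numeric(names(tab)[tab == max(tab)]))
      }
      x[hole, ci] <- fill
    }
  }
  labeled_matrix(x, data$labels, class_set = data$class_set)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Min-max feature scaling
#'
#' Maps every feature to `[0, 1]` by its observed minimum and maximum;
#' constant features map to 0. The returned parameters reproduce the
#' identical transform on held-out data via [minmax_apply()].
#'
#' @param data a [labeled_matrix()] without missing values.
#' @return List with `data` (scaled) and `params` (`min`, `max` per
#'   feature).
#' @export
minmax_scale <- function(data) {
  stopifnot(inherits(data, "labeled_matrix"))
  if (anyNA(data$features)) stop("impute missing values before scaling")
  mins <- apply(data$features, 2L, min)
  maxs <- apply(data$features, 2L, max)
  params <- list(min = mins, max = maxs)
  list(data = minmax_apply(data, params, clip = FALSE)$data, params = params)
}

#' Apply stored min-max parameters
#'
#' Transforms held-out data with training-set scaling parameters. Values
#' outside the training range land outside `[0, 1]`; with `clip = TRUE`
#' (default) they are clipped to the unit interval and flagged.
#'
#' @param data a [labeled_matrix()].
#' @param params scaling parameters from [minmax_scale()].
#' @param clip clip out-of-range values into `[0, 1]`.
#' @return List with `data` (scaled) and `clipped` (logical matrix of
#'   flagged cells; all `FALSE` when `clip = FALSE`).
#' @export
minmax_apply <- function(data, params, clip = TRUE) {
  stopifnot(inherits(data, "labeled_matrix"))
  span <- params$max - params$min
  span[span == 0] <- 1  # constant features map to 0
  scaled <- sweep(sweep(data$features, 2L, params$min), 2L, span, "/")
  clipped <- matrix(FALSE, nrow(scaled), ncol(scaled))
  if (clip) {
    clipped <- scaled < 0 | scaled > 1
    scaled[scaled < 0] <- 0
    scaled[scaled > 1] <- 1
  }
  list(data = labeled_matrix(scaled, data$labels,
                             class_set = data$class_set),
       clipped = clipped)
}

#' Invert min-max scaling
#'
#' @param data a scaled [labeled_matrix()].
#' @param params parameters from [minmax_scale()].
#' @return The `labeled_matrix` on the original scale.
#' @export
minmax_invert <- function(data, params) {
  stopifnot(inherits(data, "labeled_matrix"))
  span <- params$max - params$min
  span[span == 0] <- 1
  x <- sweep(sweep(data$features, 2L, span, "*"), 2L, params$min, "+")
  labeled_matrix(x, data$labels, class_set = data$class_set)
}

#' Write a labeled matrix as CSV
#'
#' @param data a [labeled_matrix()].
#' @param path output file.
#' @param label_column name for the class column (default `"class"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, label_column = "class") {
  stopifnot(inherits(data, "labeled_matrix"))
  df <- as.data.frame(data$features)
  if (is.null(colnames(data$features))) {
    names(df) <- paste0("f", seq_len(ncol(data$features)))
  }
  df[[label_column]] <- data$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
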