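#' Construct a feature table
#'
#' A feature table is the basic container of the package: a numeric matrix of
#' samples (rows) by features (columns) with unique feature names and unique
#' sample ids. All entries must be finite; missing or non-finite values are
#' rejected so that downstream discretization and model fitting never see
#' them.
#'
#' @param values Numeric matrix (or object coercible to one), samples in rows.
#' @param feature_names Character vector of unique column names. Defaults to
#'   the matrix column names.
#' @param sample_ids Character vector of unique row ids; auto-generated
#'   (`"sample_1"`, ...) when absent.
#' @return An object of class `feature_table`: the numeric matrix with
#'   dimnames set.
#' @export
feature_table <- function(values, feature_names = colnames(values),
                          sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("feature values must be numeric", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("feature table needs at least one sample and one feature",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature value at sample %d, feature %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(ncol(values)))
  }
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length must equal the number of columns",
         call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]),
               collapse = ", "),
         call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample_", seq_len(nrow(values)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique and match the number of rows",
         call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(values, class = c("feature_table", class(values)))
}

#' Construct a labeled dataset
#'
#' Pairs a [feature_table()] with a binary label vector (1 = editing-site /
#' positive class, 0 = negative class).
#'
#' @param table A `feature_table`.
#' @param labels Integer/numeric vector of 0s and 1s, one per sample.
#' @return An object of class `labeled_dataset`, a list with elements
#'   `table` and `labels`.
#' @export
labeled_dataset <- function(table, labels) {
  if (!inherits(table, "feature_table")) {
    table <- feature_table(table)
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(table)) {
    stop("labels length must equal the number of samples", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must contain only 0 and 1", call. = FALSE)
  }
  structure(list(table = table, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "<labeled_dataset> %d samples x %d features (%d positive, %d negative)\n",
    nrow(x$table), ncol(x$table), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$table)

#' Number of samples and features
#' @param dataset A `labeled_dataset`.
#' @return Named integer vector with `n_samples`, `n_features`,
#'   `n_positive`, `n_negative`.
#' @export
dataset_summary <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  c(n_samples = nrow(dataset$table),
    n_features = ncol(dataset$table),
    n_positive = sum(dataset$labels == 1L),
    n_negative = sum(dataset$labels == 0L))
}

#' Restrict a dataset to a feature subset
#'
#' @param dataset A `labeled_dataset`.
#' @param features Character vector of feature names (order preserved).
#' @return A `labeled_dataset` over exactly those features, in that order.
#' @export
subset_features <- function(dataset, features) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  missing <- setdiff(features, colnames(dataset$table))
  if (length(missing)) {
    stop("unknown feature name(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- dataset$table[, features, drop = FALSE]
  labeled_dataset(feature_table(tab), dataset$labels)
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L) {
    stop("training requires samples from both classes", call. = FALSE)
  }
  invisible(TRUE)
}
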