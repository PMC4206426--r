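#' Read a labeled feature table from delimited text
#'
#' Reads a CSV/TSV file with a mandatory header row into a
#' [labeled_dataset()]. The label column is removed from the feature matrix;
#' the order of the remaining columns is preserved. The delimiter is sniffed
#' from the header line (tab wins over comma when both occur) unless given
#' explicitly.
#'
#' Missing values are a hard error by default: the upstream feature
#' extraction produces complete tables, so a hole usually signals a mangled
#' file. `impute = "median"` opts in to per-feature median imputation.
#'
#' @param path Path to a delimited text file with a header row.
#' @param label_column Name of the column holding class labels.
#' @param delimiter `"auto"` (default), `","` or `"\t"`.
#' @param positive_label Value in `label_column` mapped to class 1
#'   (default `"1"`); every other value must equal `negative_label`.
#' @param negative_label Value mapped to class 0 (default `"0"`).
#' @param id_column Optional name of a sample-id column; never inferred.
#' @param impute `"none"` (default, error on missing) or `"median"`.
#' @return A `labeled_dataset`.
#' @export
read_dataset <- function(path, label_column = "label", delimiter = "auto",
                         positive_label = "1", negative_label = "0",
                         id_column = NULL, impute = c("none", "median")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (identical(delimiter, "auto")) sniff_delimiter(path) else delimiter
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found (columns: %s)", label_column,
                 paste(utils::head(names(df), 8L), collapse = ", ")),
         call. = FALSE)
  }
  raw_labels <- as.character(df[[label_column]])
  labels <- ifelse(raw_labels == as.character(positive_label), 1L,
                   ifelse(raw_labels == as.character(negative_label), 0L,
                          NA_integer_))
  if (anyNA(labels)) {
    bad <- unique(raw_labels[is.na(labels)])
    stop("unmappable label value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- NULL
  drop <- label_column
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) {
      stop(sprintf("sample-id column '%s' not found", id_column),
           call. = FALSE)
    }
    sample_ids <- as.character(df[[id_column]])
    drop <- c(drop, id_column)
  }
  feat <- df[, setdiff(names(df), drop), drop = FALSE]
  if (ncol(feat) < 1L) stop("no feature columns remain", call. = FALSE)
  non_num <- names(feat)[!vapply(feat, is.numeric, logical(1L))]
  if (length(non_num)) {
    stop("non-numeric feature column(s): ", paste(non_num, collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(feat)
  if (anyNA(mat)) {
    if (impute == "none") {
      stop("missing feature values present; re-run with impute = \"median\" ",
           "to impute per-feature medians", call. = FALSE)
    }
    for (j in seq_len(ncol(mat))) {
      nas <- is.na(mat[, j])
      if (any(nas)) mat[nas, j] <- stats::median(mat[, j], na.rm = TRUE)
    }
  }
  labeled_dataset(feature_table(mat, feature_names = colnames(mat),
                                sample_ids = sample_ids),
                  labels)
}

sniff_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

#' Write a labeled dataset as delimited text
#'
#' Inverse of [read_dataset()]: features plus a label column, header row
#' included. Values are written at full precision so a read/write round trip
#' is lossless.
#'
#' @param dataset A `labeled_dataset`.
#' @param path Output path.
#' @param label_column Name for the label column.
#' @param delimiter Field separator (default comma).
#' @export
write_dataset <- function(dataset, path, label_column = "label",
                          delimiter = ",") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- as.data.frame(unclass(dataset$table), check.names = FALSE)
  df[[label_column]] <- dataset$labels
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an mRMR ranking as TSV
#'
#' Columns: `rank` (1-based), `feature_name`, `scheme_score` (the MID/MIQ
#' objective at the step the feature was selected), `relevance` (MI with the
#' labels, bits) and `redundancy` (mean MI with previously selected
#' features, bits). Round-trips losslessly through [read_ranking()].
#'
#' @param ranking A `ranked_features` object from [rank_features()].
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranked_features"))
  df <- as.data.frame(ranking)
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranking TSV written by [write_ranking()]
#' @param path Path to the TSV.
#' @return A data frame with columns rank, feature_name, scheme_score,
#'   relevance, redundancy.
#' @export
read_ranking <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write an IFS curve as TSV
#'
#' One row per feature-set size k with columns `k`, `Sn`, `Sp`, `Acc`,
#' `MCC`. Metrics are serialized at full precision (well beyond 4 decimals)
#' so curve maxima are exactly recoverable.
#'
#' @param curve An `ifs_curve` object from [ifs_curve()].
#' @param path Output path.
#' @export
write_ifs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ifs_curve"))
  df <- as.data.frame(curve)
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an IFS curve TSV written by [write_ifs_curve()]
#' @param path Path to the TSV.
#' @return A data frame with columns k, Sn, Sp, Acc, MCC.
#' @export
read_ifs_curve <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
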