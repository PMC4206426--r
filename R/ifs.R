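#' Incremental feature selection (IFS) curve
#'
#' Sweeps k = 1..N over the mRMR ranking: for each k the top-k features are
#' cross-validated with the forest classifier and the pooled metrics
#' recorded. The same CV seed -- hence the same fold assignment -- is used
#' at every k, so consecutive points differ only in the feature set (a
#' paired comparison that removes fold-assignment noise from the curve
#' shape). The optimal k is the smallest k achieving the maximum MCC.
#'
#' @param dataset A `labeled_dataset`.
#' @param ranking A `ranked_features` covering all dataset features.
#' @param rf An [rf_config()].
#' @param cv A [cv_config()].
#' @param paired_folds Reuse the same fold assignment for every k (default);
#'   `FALSE` re-derives folds from a k-specific seed.
#' @return An `ifs_curve`: list with `k`, `Sn`, `Sp`, `Acc`, `MCC` vectors
#'   over k = 1..N, plus `optimal_k` and `optimal_metrics`.
#' @export
ifs_curve <- function(dataset, ranking, rf = rf_config(),
                      cv = cv_config(), paired_folds = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(ranking, "ranked_features"))
  if (!setequal(ranking$feature_names, colnames(dataset$table))) {
    stop("ranking must cover exactly the dataset's features", call. = FALSE)
  }
  n_feat <- length(ranking$feature_names)
  mat <- matrix(NA_real_, n_feat, 4L,
                dimnames = list(NULL, c("Sn", "Sp", "Acc", "MCC")))
  for (k in seq_len(n_feat)) {
    cv_k <- cv
    if (!paired_folds) cv_k$seed <- fold_seed(cv$seed, k)
    m <- cross_validate(dataset, ranking$feature_names[seq_len(k)],
                        rf = rf, cv = cv_k)
    mat[k, ] <- m[c("Sn", "Sp", "Acc", "MCC")]
  }
  optimal_k <- which.max(mat[, "MCC"])  # first max => smallest k
  structure(list(k = seq_len(n_feat),
                 Sn = mat[, "Sn"], Sp = mat[, "Sp"],
                 Acc = mat[, "Acc"], MCC = mat[, "MCC"],
                 optimal_k = optimal_k,
                 optimal_metrics = structure(mat[optimal_k, ],
                                             class = "metric_set")),
            class = "ifs_curve")
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat(sprintf(
    "<ifs_curve> %d points; optimal k = %d (MCC = %.4f, Acc = %.4f)\n",
    length(x$k), x$optimal_k, x$optimal_metrics[["MCC"]],
    x$optimal_metrics[["Acc"]]))
  invisible(x)
}

#' @export
as.data.frame.ifs_curve <- function(x, ...) {
  data.frame(k = x$k, Sn = x$Sn, Sp = x$Sp, Acc = x$Acc, MCC = x$MCC)
}

#' Train the final model on the optimal feature set
#'
#' Retrains once on the full dataset restricted to the top `optimal_k`
#' ranked features identified by the IFS sweep.
#'
#' @param dataset The `labeled_dataset` the curve was computed on.
#' @param curve An `ifs_curve`.
#' @param ranking The `ranked_features` used for the curve.
#' @param rf An [rf_config()].
#' @return An `edit_rf_model` over exactly the optimal feature set.
#' @export
select_final_model <- function(dataset, curve, ranking, rf = rf_config()) {
  stopifnot(inherits(curve, "ifs_curve"))
  train_model(dataset, ranking$feature_names[seq_len(curve$optimal_k)], rf)
}
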