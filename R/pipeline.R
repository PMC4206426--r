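#' Evaluate a trained model on a labeled dataset
#'
#' @param model An `edit_rf_model`.
#' @param dataset A `labeled_dataset` containing the model's features.
#' @return A `metric_set` with a `counts` attribute.
#' @export
evaluate_model <- function(model, dataset) {
  stopifnot(inherits(model, "edit_rf_model"),
            inherits(dataset, "labeled_dataset"))
  preds <- predict(model, dataset$table)
  counts <- confusion(dataset$labels, preds)
  metrics <- compute_metrics(counts)
  attr(metrics, "counts") <- counts
  metrics
}

#' Run the full ranking / IFS / final-model pipeline
#'
#' End-to-end driver: mRMR-rank the training features, sweep the IFS curve
#' under cross-validation, train the final model on the full training set
#' restricted to the optimal feature set, and (when a testing dataset is
#' supplied) evaluate that model on it. When `out_dir` is given, writes
#' `ranking.tsv`, `ifs_curve.tsv`, `selected_features.txt`, `report.tsv`
#' and `model.bin` there; outputs are byte-identical across runs with the
#' same configuration and seeds.
#'
#' @param train A `labeled_dataset` used for ranking, IFS and final training.
#' @param test Optional `labeled_dataset` for independent evaluation.
#' @param scheme mRMR criterion, `"MID"` or `"MIQ"`.
#' @param threshold_multiplier Discretization threshold t.
#' @param rf An [rf_config()].
#' @param cv A [cv_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list with `ranking`, `curve`, `model`, `training_metrics`
#'   (CV metrics at the optimal k) and, if `test` was given,
#'   `testing_metrics`.
#' @export
run_pipeline <- function(train, test = NULL, scheme = "MID",
                         threshold_multiplier = 1, rf = rf_config(),
                         cv = cv_config(), out_dir = NULL) {
  stopifnot(inherits(train, "labeled_dataset"))
  ranking <- rank_features(train, scheme = scheme,
                           threshold_multiplier = threshold_multiplier)
  curve <- ifs_curve(train, ranking, rf = rf, cv = cv)
  model <- select_final_model(train, curve, ranking, rf = rf)
  result <- list(ranking = ranking, curve = curve, model = model,
                 training_metrics = curve$optimal_metrics,
                 optimal_k = curve$optimal_k)
  if (!is.null(test)) {
    stopifnot(inherits(test, "labeled_dataset"))
    result$testing_metrics <- evaluate_model(model, test)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ranking(ranking, file.path(out_dir, "ranking.tsv"))
    write_ifs_curve(curve, file.path(out_dir, "ifs_curve.tsv"))
    writeLines(model$feature_names,
               file.path(out_dir, "selected_features.txt"))
    write_report(result, file.path(out_dir, "report.tsv"))
    save_model(model, file.path(out_dir, "model.bin"))
  }
  result
}

# Table-1-style report: one training (CV) row, one testing row if present.
write_report <- function(result, path) {
  rows <- data.frame(dataset = "Training",
                     features = result$optimal_k,
                     Sn = result$training_metrics[["Sn"]],
                     Sp = result$training_metrics[["Sp"]],
                     Acc = result$training_metrics[["Acc"]],
                     MCC = result$training_metrics[["MCC"]])
  if (!is.null(result$testing_metrics)) {
    rows <- rbind(rows, data.frame(
      dataset = "Testing", features = result$optimal_k,
      Sn = result$testing_metrics[["Sn"]],
      Sp = result$testing_metrics[["Sp"]],
      Acc = result$testing_metrics[["Acc"]],
      MCC = result$testing_metrics[["MCC"]]))
  }
  utils::write.table(format(rows, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
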