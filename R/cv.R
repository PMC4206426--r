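#' Cross-validation configuration
#'
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param stratified Shuffle and deal folds within each class (default),
#'   keeping per-fold class ratios within one sample of the overall ratio.
#' @param pooled Pool all folds' test predictions into one confusion matrix
#'   before computing metrics (default); `FALSE` averages per-fold metrics
#'   instead.
#' @return A `cv_config` list.
#' @export
cv_config <- function(folds = 10L, seed = 1L, stratified = TRUE,
                      pooled = TRUE) {
  folds <- as.integer(folds)
  stopifnot(folds >= 2L)
  structure(list(folds = folds, seed = as.integer(seed),
                 stratified = isTRUE(stratified), pooled = isTRUE(pooled)),
            class = "cv_config")
}

#' Assign samples to cross-validation folds
#'
#' Stratified mode shuffles each class separately (seeded) and deals its
#' members round-robin across folds, carrying the dealing offset from one
#' class to the next so leftover samples spread evenly: at 127 + 127
#' samples and 10 folds this yields fold sizes of 25 or 26 with per-fold
#' class counts within one of balance.
#'
#' @param labels Binary label vector.
#' @param config A [cv_config()].
#' @return Integer vector of fold ids (1..folds), one per sample.
#' @export
make_folds <- function(labels, config = cv_config()) {
  n <- length(labels)
  k <- config$folds
  if (k > n) stop("more folds than samples", call. = FALSE)
  fold <- integer(n)
  if (config$stratified) {
    classes <- sort(unique(labels))
    smallest <- min(table(labels))
    if (smallest < k) {
      stop(sprintf(
        "smallest class has %d samples, fewer than %d folds", smallest, k),
        call. = FALSE)
    }
    offset <- 0L
    with_seed(config$seed, {
      for (cl in classes) {
        members <- which(labels == cl)
        members <- members[sample.int(length(members))]
        fold[members] <- ((offset + seq_along(members) - 1L) %% k) + 1L
        offset <- (offset + length(members)) %% k
      }
    })
  } else {
    with_seed(config$seed, {
      perm <- sample.int(n)
      fold[perm] <- ((seq_len(n) - 1L) %% k) + 1L
    })
  }
  fold
}

#' Cross-validate a random-forest model over a feature subset
#'
#' Runs k-fold cross-validation: each fold in turn is held out, a forest is
#' trained on the remaining folds, and the held-out samples are predicted.
#' By default all folds' predictions are pooled into a single confusion
#' matrix covering every sample exactly once, and the metrics are computed
#' once from it (micro-averaged CV) -- with small folds this is far more
#' stable than averaging per-fold MCCs. Fully deterministic given the CV
#' and forest seeds.
#'
#' @param dataset A `labeled_dataset`.
#' @param feature_subset Feature names to use; defaults to all.
#' @param rf An [rf_config()]; each fold's forest gets a seed derived
#'   deterministically from it.
#' @param cv A [cv_config()].
#' @return A `metric_set` with attributes `counts` (pooled
#'   `confusion_counts`) and `predictions` (out-of-fold prediction per
#'   sample).
#' @export
cross_validate <- function(dataset, feature_subset = colnames(dataset$table),
                           rf = rf_config(), cv = cv_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  ds <- subset_features(dataset, feature_subset)
  fold <- make_folds(ds$labels, cv)
  n <- nrow(ds$table)
  preds <- integer(n)
  fold_metrics <- vector("list", cv$folds)
  for (f in seq_len(cv$folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    train_ds <- labeled_dataset(
      feature_table(ds$table[train_idx, , drop = FALSE],
                    feature_names = colnames(ds$table)),
      ds$labels[train_idx])
    fold_rf <- rf
    fold_rf$seed <- fold_seed(rf$seed, f)
    model <- train_model(train_ds, feature_subset, fold_rf)
    preds[test_idx] <- predict(model,
                               ds$table[test_idx, , drop = FALSE])
    if (!cv$pooled) {
      fold_metrics[[f]] <-
        compute_metrics(confusion(ds$labels[test_idx], preds[test_idx]))
    }
  }
  counts <- confusion(ds$labels, preds)
  metrics <- if (cv$pooled) {
    compute_metrics(counts)
  } else {
    m <- do.call(rbind, fold_metrics)
    structure(colMeans(m, na.rm = TRUE), class = "metric_set")
  }
  attr(metrics, "counts") <- counts
  attr(metrics, "predictions") <- preds
  metrics
}

# Deterministic per-fold seed; kept well inside 32-bit integer range.
fold_seed <- function(seed, fold) {
  as.integer((as.numeric(seed) * 1009 + fold * 9176) %% 2147483647)
}
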