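#' Random-forest configuration
#'
#' Defaults mirror the classic Weka 3.6.4 RandomForest settings: 10 trees,
#' unlimited depth, and floor(log2(M)) + 1 candidate features per split for
#' an M-feature set. Ten trees keep the historical behaviour; raising
#' `n_trees` (e.g. to 100) reduces cross-validation variance and is a
#' sensible modern choice.
#'
#' @param n_trees Number of trees (>= 1, default 10).
#' @param features_per_split `"log2"` (default, the floor(log2(M)) + 1 rule)
#'   or a positive integer, capped at M at fit time.
#' @param seed Integer seed making training deterministic.
#' @param max_depth Maximum tree depth; `Inf` (default) grows unpruned trees.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 10L, features_per_split = "log2",
                      seed = 1L, max_depth = Inf) {
  n_trees <- as.integer(n_trees)
  stopifnot(n_trees >= 1L)
  if (!identical(features_per_split, "log2")) {
    features_per_split <- as.integer(features_per_split)
    stopifnot(features_per_split >= 1L)
  }
  structure(list(n_trees = n_trees, features_per_split = features_per_split,
                 seed = as.integer(seed), max_depth = max_depth),
            class = "rf_config")
}

mtry_for <- function(config, n_features) {
  m <- if (identical(config$features_per_split, "log2")) {
    floor(log2(n_features)) + 1L
  } else {
    config$features_per_split
  }
  max(1L, min(as.integer(m), n_features))
}

# Run expr under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Train a random-forest editing-site classifier
#'
#' Fits a seeded bagged ensemble of decision trees on the dataset restricted
#' to `feature_subset` (order preserved). Training is deterministic given
#' (data, subset, seed). The fitted model records its feature names and
#' aligns prediction inputs to them by name.
#'
#' @param dataset A `labeled_dataset` containing both classes.
#' @param feature_subset Character vector of feature names to train on;
#'   defaults to all features.
#' @param config An [rf_config()].
#' @return An `edit_rf_model`.
#' @export
train_model <- function(dataset, feature_subset = colnames(dataset$table),
                        config = rf_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "rf_config"))
  if (length(feature_subset) < 1L) {
    stop("feature_subset must be non-empty", call. = FALSE)
  }
  check_two_classes(dataset$labels)
  ds <- subset_features(dataset, feature_subset)
  y <- factor(ds$labels, levels = c(0L, 1L))
  x <- as.data.frame(unclass(ds$table), check.names = FALSE)
  nodesize <- 1L
  fit <- with_seed(config$seed,
    randomForest::randomForest(
      x = x, y = y,
      ntree = config$n_trees,
      mtry = mtry_for(config, ncol(x)),
      nodesize = nodesize,
      maxnodes = if (is.finite(config$max_depth)) 2L^config$max_depth
                 else NULL,
      replace = TRUE))
  structure(list(fit = fit, feature_names = feature_subset,
                 config = config),
            class = "edit_rf_model")
}

#' @export
print.edit_rf_model <- function(x, ...) {
  cat(sprintf("<edit_rf_model> %d trees over %d features (seed %d)\n",
              x$config$n_trees, length(x$feature_names), x$config$seed))
  invisible(x)
}

#' Predict class labels with a trained model
#'
#' Majority vote over trees; an exact tie is resolved to the negative class
#' so predictions are deterministic even with an even number of trees.
#'
#' @param object An `edit_rf_model`.
#' @param table A `feature_table` (or numeric matrix with column names)
#'   containing at least the model's feature columns.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions, one per row.
#' @export
predict.edit_rf_model <- function(object, table, ...) {
  mat <- unclass(as.matrix(table))
  missing <- setdiff(object$feature_names, colnames(mat))
  if (length(missing)) {
    stop("table lacks model feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(mat[, object$feature_names, drop = FALSE],
                     check.names = FALSE)
  votes <- stats::predict(object$fit, newdata = x, type = "vote",
                          norm.votes = TRUE)
  as.integer(votes[, "1"] > 0.5)
}

#' Save / load a trained model as plain text
#'
#' Serializes the fitted ensemble together with its configuration and
#' feature names into a single self-contained file.
#'
#' @param model An `edit_rf_model`.
#' @param path Destination file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "edit_rf_model"))
  con <- file(path, "wb")
  on.exit(close(con))
  serialize(model, con)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the `edit_rf_model`.
#' @export
load_model <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  model <- unserialize(con)
  stopifnot(inherits(model, "edit_rf_model"))
  model
}
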