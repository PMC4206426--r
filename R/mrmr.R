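#' Rank features by Maximum Relevance Minimum Redundancy (mRMR)
#'
#' Greedy forward ranking of all features. Relevance of a feature is its
#' mutual information with the class labels; redundancy is the mean mutual
#' information with the already-selected features, both computed on the
#' discretized table. Step 1 picks the most relevant feature; step k > 1
#' picks the unselected feature maximizing
#'
#' * MID (difference form, default): relevance - mean redundancy
#' * MIQ (quotient form): relevance / max(mean redundancy, epsilon)
#'
#' Ties are broken toward the lowest original column index, making the
#' ordering fully deterministic. All features are ranked, from the best
#' relevance/redundancy trade-off down to the worst.
#'
#' @param dataset A `labeled_dataset` with both classes present and >= 2
#'   features.
#' @param scheme `"MID"` or `"MIQ"`.
#' @param threshold_multiplier Discretization threshold t (see
#'   [discretize_feature()]).
#' @param passthrough_levels See [discretize_table()].
#' @param epsilon Floor for the MIQ mean redundancy (default 1e-12).
#' @return A `ranked_features` object: list with `order` (integer column
#'   indices in rank order), `feature_names` (in rank order), `relevance`
#'   (per ranked feature, bits), `redundancy` (mean MI with the features
#'   ranked before it, bits; 0 for the first), `step_score` (the scheme
#'   objective at selection time) and `scheme`.
#' @export
rank_features <- function(dataset, scheme = c("MID", "MIQ"),
                          threshold_multiplier = 1, passthrough_levels = 3L,
                          epsilon = 1e-12) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "labeled_dataset"))
  check_two_classes(dataset$labels)
  n_feat <- ncol(dataset$table)
  if (n_feat < 1L) stop("at least one feature required", call. = FALSE)

  states <- discretize_table(dataset$table, threshold_multiplier,
                             passthrough_levels)
  relevance <- vapply(seq_len(n_feat),
                      function(j) mutual_information(states[, j],
                                                     dataset$labels),
                      numeric(1L))

  order_idx <- integer(n_feat)
  step_score <- numeric(n_feat)
  mean_red <- numeric(n_feat)
  red_sum <- numeric(n_feat)      # running sum of MI with selected features
  remaining <- rep(TRUE, n_feat)

  for (k in seq_len(n_feat)) {
    cand <- which(remaining)
    if (k == 1L) {
      score <- relevance[cand]
      red <- rep(0, length(cand))
    } else {
      red <- red_sum[cand] / (k - 1L)
      score <- if (scheme == "MID") relevance[cand] - red
               else relevance[cand] / pmax(red, epsilon)
    }
    pick <- cand[which.max(score)]  # which.max takes the first => lowest index
    order_idx[k] <- pick
    step_score[k] <- score[which.max(score)]
    mean_red[k] <- red[which(cand == pick)]
    remaining[pick] <- FALSE
    if (k < n_feat) {
      rest <- which(remaining)
      red_sum[rest] <- red_sum[rest] +
        vapply(rest, function(j) mutual_information(states[, j],
                                                    states[, pick]),
               numeric(1L))
    }
  }

  structure(list(order = order_idx,
                 feature_names = colnames(dataset$table)[order_idx],
                 relevance = relevance[order_idx],
                 redundancy = mean_red,
                 step_score = step_score,
                 scheme = scheme),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features> %d features, scheme %s\n",
              length(x$order), x$scheme))
  print(utils::head(as.data.frame(x), 10L))
  if (length(x$order) > 10L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.ranked_features <- function(x, ...) {
  data.frame(rank = seq_along(x$order),
             feature_name = x$feature_names,
             scheme_score = x$step_score,
             relevance = x$relevance,
             redundancy = x$redundancy,
             stringsAsFactors = FALSE)
}

#' Top-k feature names from a ranking
#' @param ranking A `ranked_features` object.
#' @param k Number of top features.
#' @return Character vector of length k.
#' @export
top_features <- function(ranking, k) {
  stopifnot(inherits(ranking, "ranked_features"),
            k >= 1L, k <= length(x = ranking$order))
  ranking$feature_names[seq_len(k)]
}
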