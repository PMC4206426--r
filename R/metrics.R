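#' Confusion counts from labels and predictions
#'
#' @param labels,predictions Equal-length binary (0/1) vectors; 1 is the
#'   positive (editing-site) class.
#' @return A `confusion_counts` object: named integer vector with `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("length mismatch", call. = FALSE)
  }
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (!all(labels %in% c(0L, 1L)) || !all(predictions %in% c(0L, 1L))) {
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  }
  structure(c(TP = sum(labels == 1L & predictions == 1L),
              TN = sum(labels == 0L & predictions == 0L),
              FP = sum(labels == 0L & predictions == 1L),
              FN = sum(labels == 1L & predictions == 0L)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Standard binary-classification measures:
#' \deqn{Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP), \quad
#'       Acc = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'       \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#'
#' MCC is the main evaluator for this pipeline: it stays informative on the
#' unbalanced testing data where accuracy alone can be misleading. When any
#' factor of the MCC denominator is zero the MCC is defined as 0 (standard
#' convention). Sn (resp. Sp) is `NaN` when there are no positives (resp.
#' negatives) to evaluate.
#'
#' @param counts A `confusion_counts` object, or a named vector with TP,
#'   TN, FP, FN.
#' @return A `metric_set`: named numeric vector with `Sn`, `Sp`, `Acc`,
#'   `MCC`.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + tn + fp + fn
  if (total <= 0) stop("no evaluated samples", call. = FALSE)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NaN
  sp <- if (tn + fp > 0) tn / (tn + fp) else NaN
  acc <- (tp + tn) / total
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0
  structure(c(Sn = sn, Sp = sp, Acc = acc, MCC = mcc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 3L, ...) {
  cat(sprintf("Sn = %.*f  Sp = %.*f  Acc = %.*f  MCC = %.*f\n",
              digits, x[["Sn"]], digits, x[["Sp"]],
              digits, x[["Acc"]], digits, x[["MCC"]]))
  invisible(x)
}
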